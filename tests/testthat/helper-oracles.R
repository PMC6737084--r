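# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (quaternion superposition instead of bio3d /
# Kabsch, double loops instead of matrix algebra) so the tests are a genuine
# cross-check.

# Horn quaternion method: optimal rotation + translation of `mob` onto `ref`
horn_superpose <- function(ref, mob) {
  cr <- colMeans(ref); cm <- colMeans(mob)
  a <- sweep(mob, 2, cm); b <- sweep(ref, 2, cr)
  s <- t(a) %*% b
  key <- matrix(0, 4, 4)
  key[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  key[1, 2] <- key[2, 1] <- s[2, 3] - s[3, 2]
  key[1, 3] <- key[3, 1] <- s[3, 1] - s[1, 3]
  key[1, 4] <- key[4, 1] <- s[1, 2] - s[2, 1]
  key[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  key[2, 3] <- key[3, 2] <- s[1, 2] + s[2, 1]
  key[2, 4] <- key[4, 2] <- s[1, 3] + s[3, 1]
  key[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  key[3, 4] <- key[4, 3] <- s[2, 3] + s[3, 2]
  key[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(key, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  sweep(a %*% t(rot), 2, cr, "+")
}

oracle_rmsd <- function(a, b, fit = FALSE) {
  if (fit) b <- horn_superpose(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

# double-loop scalar covariance / Pearson cross-correlation
oracle_cov_cc <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  means <- apply(coords, c(2, 3), mean)
  cov <- matrix(0, na, na)
  for (i in seq_len(na)) {
    for (j in seq_len(na)) {
      acc <- 0
      for (t in seq_len(nf)) {
        acc <- acc + sum((coords[t, i, ] - means[i, ]) *
                           (coords[t, j, ] - means[j, ]))
      }
      cov[i, j] <- acc / nf
    }
  }
  cc <- matrix(0, na, na)
  for (i in seq_len(na)) {
    for (j in seq_len(na)) {
      if (cov[i, i] > 0 && cov[j, j] > 0) {
        cc[i, j] <- cov[i, j] / sqrt(cov[i, i] * cov[j, j])
      }
    }
  }
  list(cov = cov, cc = cc)
}

# exhaustive greedy clustering on a precomputed distance matrix, with the
# lowest-index tie-break
oracle_daura <- function(d, cutoff) {
  nf <- nrow(d)
  remaining <- seq_len(nf)
  assignments <- integer(nf)
  centroids <- integer(0)
  k <- 0
  while (length(remaining) > 0) {
    best_count <- -1; best <- NA
    for (f in remaining) {
      cnt <- sum(d[f, setdiff(remaining, f)] <= cutoff)
      if (cnt > best_count) { best_count <- cnt; best <- f }
    }
    members <- remaining[d[best, remaining] <= cutoff | remaining == best]
    k <- k + 1
    assignments[members] <- k
    centroids <- c(centroids, best)
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(assignments, k)
  ord <- order(-sizes, centroids)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(assignments = relabel[assignments], centroids = centroids[ord],
       sizes = sizes[ord])
}

# exhaustive minimax-path barrier on a small grid (path enumeration by
# repeated relaxation, 4-neighbour moves)
oracle_minimax <- function(values, start, goal) {
  # values: matrix; start/goal: c(i, j). Bellman-Ford style relaxation of the
  # minimax cost.
  ni <- nrow(values); nj <- ncol(values)
  cost <- matrix(Inf, ni, nj)
  cost[start[1], start[2]] <- values[start[1], start[2]]
  for (iter in seq_len(ni * nj)) {
    changed <- FALSE
    for (i in seq_len(ni)) {
      for (j in seq_len(nj)) {
        for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
          if (nb[1] < 1 || nb[1] > ni || nb[2] < 1 || nb[2] > nj) next
          cand <- max(cost[nb[1], nb[2]], values[i, j])
          if (cand < cost[i, j]) { cost[i, j] <- cand; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  cost[goal[1], goal[2]]
}

random_trajectory <- function(n_atoms = 10, n_frames = 5, seed = 1,
                              spread = 4) {
  set.seed(seed)
  top <- ercoupler::make_topology(atom_name = "CA",
                                  residue_index = seq_len(n_atoms),
                                  element = "C")
  coords <- array(stats::rnorm(n_frames * n_atoms * 3, sd = spread),
                  dim = c(n_frames, n_atoms, 3))
  ercoupler::new_trajectory(top, coords)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
}

transform_trajectory <- function(traj, rot, shift, per_frame = FALSE,
                                 seed = 99) {
  coords <- traj$coords
  if (per_frame) set.seed(seed)
  for (k in seq_len(dim(coords)[1])) {
    if (per_frame) {
      rot <- random_rotation()
      shift <- stats::rnorm(3, sd = 10)
    }
    fr <- coords[k, , ]
    dim(fr) <- dim(coords)[2:3]
    coords[k, , ] <- sweep(fr %*% t(rot), 2, shift, "+")
  }
  ercoupler::new_trajectory(traj$topology, coords, traj$times)
}

# frames drawn as tight noise around well-separated templates; frames_per is
# recycled over templates (unequal sizes make extraction order deterministic)
clustered_trajectory <- function(n_templates, frames_per, noise, seed = 1,
                                 n_atoms = 6) {
  set.seed(seed)
  templates <- lapply(seq_len(n_templates), function(k)
    matrix(stats::rnorm(n_atoms * 3, sd = 6), n_atoms, 3))
  sizes <- rep_len(frames_per, n_templates)
  which_t <- rep(seq_len(n_templates), times = sizes)
  nf <- length(which_t)
  coords <- array(0, dim = c(nf, n_atoms, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- templates[[which_t[f]]] +
      stats::rnorm(n_atoms * 3, sd = noise)
  }
  ercoupler::new_trajectory(
    ercoupler::make_topology("CA", seq_len(n_atoms), element = "C"), coords)
}

write_minimal_pdb <- function(path, n_res = 3, with_h = FALSE) {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(n_res)) {
    for (nm in c("N", "CA", "C", if (with_h) "H")) {
      serial <- serial + 1
      el <- substr(nm, 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, r, r * 3.8, serial * 0.5, 0, el))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
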