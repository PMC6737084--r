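#' Atomic covariance matrix of positional fluctuations
#'
#' For atoms i and j the covariance is the time average of the dot product of
#' their mean-free position vectors,
#' \deqn{C_{ij} = \langle (\vec r_i - \langle \vec r_i\rangle)\cdot
#'               (\vec r_j - \langle \vec r_j\rangle) \rangle ,}
#' in Angstrom^2 — the scalar (dot-product) form, not the 3n x 3n Cartesian
#' covariance. The trajectory is expected to be RMS-fit first (see
#' [rms_fit_trajectory()]); the function does not fit.
#'
#' The conventional choice for dynamic cross-correlation maps is one
#' representative atom per residue, typically C-alpha; pass that selection
#' here (see [resolve_selection()]).
#'
#' @param traj a `trajectory`, already RMS-fit.
#' @param selection atom ids to include (rows/columns of the matrix).
#' @param window optional inclusive frame range `c(first, last)`; default all
#'   frames. At least 2 frames are required.
#' @return a `covariance_matrix`: list with `values` (symmetric n x n,
#'   Angstrom^2), `atom_ids`.
#' @export
covariance_matrix <- function(traj, selection = NULL, window = NULL) {
  top <- traj$topology
  ids <- if (is.null(selection)) top$atom_id else as_selection_ids(selection, top)
  if (length(ids) < 1) stop("empty selection")
  if (is.null(window)) window <- c(1L, n_frames(traj))
  frames <- seq(window[1], window[2])
  if (length(frames) < 2) {
    stop("insufficient data: covariance needs a window of at least 2 frames")
  }
  nf <- length(frames)
  # C = sum over the 3 coordinates of the (divisor-N) coordinate covariances
  vals <- matrix(0, length(ids), length(ids))
  for (d in 1:3) {
    x <- traj$coords[frames, ids, d, drop = FALSE]
    dim(x) <- c(nf, length(ids))
    x <- sweep(x, 2, colMeans(x))
    vals <- vals + crossprod(x) / nf
  }
  vals <- (vals + t(vals)) / 2
  structure(list(values = vals, atom_ids = ids), class = "covariance_matrix")
}

#' Normalize a covariance matrix to Pearson cross-correlations (DCCM)
#'
#' \deqn{CC_{ij} = C_{ij} / \sqrt{C_{ii} C_{jj}}} so that −1 means fully
#' anti-correlated and +1 lockstep motion. Atoms with zero positional variance
#' cannot be normalized: their off-diagonal entries are set to 0 and their ids
#' are recorded in `zero_variance_atoms` (with a warning) instead of
#' propagating NaN.
#'
#' @param cov a `covariance_matrix`.
#' @return a `cross_correlation`: list with `values` (n x n, entries in
#'   \[−1, 1\], unit diagonal for atoms with variance), `atom_ids`,
#'   `zero_variance_atoms`.
#' @export
cross_correlation_matrix <- function(cov) {
  v <- cov$values
  if (max(abs(v - t(v))) > 1e-10) stop("covariance matrix is not symmetric")
  d <- diag(v)
  zero <- d <= 0
  s <- sqrt(ifelse(zero, 1, d))
  cc <- v / outer(s, s)
  cc[zero, ] <- 0
  cc[, zero] <- 0
  diag(cc)[!zero] <- 1
  cc <- pmin(pmax(cc, -1), 1)
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s) excluded from normalization")
  }
  structure(list(values = cc, atom_ids = cov$atom_ids,
                 zero_variance_atoms = cov$atom_ids[zero]),
            class = "cross_correlation")
}

# map the rows of a cross-correlation matrix to residues; requires one
# representative atom per residue (the DCCM convention)
cc_residue_keys <- function(cc, topology) {
  idx <- match(cc$atom_ids, topology$atom_id)
  keys <- paste(topology$chain_id[idx], topology$residue_index[idx])
  if (anyDuplicated(keys)) {
    stop("segment scoring requires one representative atom per residue ",
         "(e.g. a C-alpha selection)")
  }
  tibble::tibble(row = seq_along(idx),
                 chain_id = topology$chain_id[idx],
                 residue_index = topology$residue_index[idx])
}

#' Noise-filtered inter-segment correlation scores
#'
#' For every pair of segments (helices) I, J the score is the sum of
#' cross-correlations over residue pairs (i in I, j in J) that survive the
#' noise filter |CC_ij| >= `threshold`, divided by the product of the numbers
#' of residues of I and J that contribute at least one surviving pair (the
#' "correlation density" normalization). Pairs with −threshold < CC <
#' +threshold are discarded as uncorrelated noise; a segment pair with no
#' surviving residue pair scores 0.
#'
#' @param cc a `cross_correlation` over one representative atom per residue.
#' @param topology the matching `topology`.
#' @param segments a `segment_map`.
#' @param threshold noise cutoff on |CC| (inclusive), default 0.6.
#' @param density_normalizer `"contributing"` (default: residues with at least
#'   one surviving pair) or `"all"` (every residue of the segment).
#' @param include_self include the I == J diagonal entries (distinct residue
#'   pairs counted once)?
#' @return a `segment_correlation` tibble with columns `segment_i`,
#'   `segment_j`, `score`, `n_contributing_pairs`, `n_residues_i`,
#'   `n_residues_j`; attribute `threshold`.
#' @export
segment_correlation_score <- function(cc, topology, segments, threshold = 0.6,
                                      density_normalizer = c("contributing",
                                                             "all"),
                                      include_self = FALSE) {
  density_normalizer <- match.arg(density_normalizer)
  keys <- cc_residue_keys(cc, topology)
  seg_rows <- lapply(segments$segment_name, function(nm) {
    res <- segment_residues(segments, nm)
    rows <- keys$row[keys$chain_id %in% res$chain_id &
                       keys$residue_index %in% res$residue_index]
    rows[order(keys$residue_index[match(rows, keys$row)])]
  })
  names(seg_rows) <- segments$segment_name
  empty <- names(seg_rows)[lengths(seg_rows) == 0]
  if (length(empty) > 0) {
    stop("segment(s) with no resolvable residues: ",
         paste(empty, collapse = ", "))
  }
  nm <- segments$segment_name
  pairs <- tidyr::expand_grid(i = seq_along(nm), j = seq_along(nm)) |>
    dplyr::filter(if (include_self) .data$i <= .data$j else .data$i < .data$j)
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    ri <- seg_rows[[i]]; rj <- seg_rows[[j]]
    block <- cc$values[ri, rj, drop = FALSE]
    if (i == j) {
      mask <- upper.tri(block)                 # distinct residue pairs once
    } else {
      mask <- matrix(TRUE, nrow(block), ncol(block))
    }
    keep <- mask & abs(block) >= threshold
    n_pairs <- sum(keep)
    if (n_pairs == 0) {
      score <- 0
      nri <- nrj <- 0L
    } else {
      contrib_i <- which(rowSums(keep) > 0)
      contrib_j <- which(colSums(keep) > 0)
      nri <- if (density_normalizer == "all") length(ri) else length(contrib_i)
      nrj <- if (density_normalizer == "all") length(rj) else length(contrib_j)
      score <- sum(block[keep]) / (nri * nrj)
    }
    tibble::tibble(segment_i = nm[i], segment_j = nm[j], score = score,
                   n_contributing_pairs = as.integer(n_pairs),
                   n_residues_i = as.integer(nri),
                   n_residues_j = as.integer(nrj))
  })
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("segment_correlation", class(out)))
  out
}

#' Per-residue correlation profile against a focus segment
#'
#' For each residue outside the focus segment (e.g. H12), the sum of its
#' cross-correlations to all focus-segment residues, keeping only entries with
#' |CC| >= `threshold` (set `threshold = 0` for the unfiltered sum).
#'
#' @inheritParams segment_correlation_score
#' @param focus_segment segment name to profile against.
#' @return tibble `chain_id`, `residue_index`, `score`, `n_contributing`.
#' @export
per_residue_profile <- function(cc, topology, focus_segment, segments,
                                threshold = 0.6) {
  keys <- cc_residue_keys(cc, topology)
  res <- segment_residues(segments, focus_segment)
  focus_rows <- keys$row[keys$chain_id %in% res$chain_id &
                           keys$residue_index %in% res$residue_index]
  if (length(focus_rows) == 0) {
    stop("focus segment has no resolvable residues: ", focus_segment)
  }
  others <- setdiff(keys$row, focus_rows)
  block <- cc$values[others, focus_rows, drop = FALSE]
  keep <- abs(block) >= threshold
  out <- tibble::tibble(
    chain_id = keys$chain_id[match(others, keys$row)],
    residue_index = keys$residue_index[match(others, keys$row)],
    score = rowSums(block * keep),
    n_contributing = as.integer(rowSums(keep))
  )
  attr(out, "focus_segment") <- focus_segment
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("residue_profile", class(out)))
  out
}

#' Eigen-decomposition summary of a covariance matrix
#'
#' Reports the sorted eigenvalues and the fraction of total positional
#' variance each collective eigenvector carries. Purely descriptive; no PCA
#' projection is performed downstream.
#'
#' @param cov a `covariance_matrix`.
#' @return tibble `mode`, `eigenvalue`, `fraction_variance`,
#'   `cumulative_fraction`.
#' @export
covariance_eigen <- function(cov) {
  ev <- sort(eigen(cov$values, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tot <- sum(pmax(ev, 0))
  tibble::tibble(mode = seq_along(ev), eigenvalue = ev,
                 fraction_variance = pmax(ev, 0) / tot,
                 cumulative_fraction = cumsum(pmax(ev, 0) / tot))
}
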