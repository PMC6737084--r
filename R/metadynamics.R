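#' Collective-variable specification
#'
#' Two CV kinds mirror the dissociation setup used for antiestrogens leaving
#' the ligand-binding cavity: a contact coordination number between two atom
#' groups (H-bond or hydrophobic contacts, CV1) and the centre-of-mass
#' distance between the groups in nm (CV2).
#'
#' @param kind `"coordination_number"` or `"com_distance"`.
#' @param group_a,group_b disjoint, non-empty integer atom-id groups.
#' @param r0 switching radius in Angstrom (coordination only).
#' @param n,m rational-switch exponents, `m > n > 0` (defaults 6 and 12).
#' @return a `cv_spec` list.
#' @export
cv_spec <- function(kind = c("coordination_number", "com_distance"),
                    group_a, group_b, r0 = 3.5, n = 6L, m = 12L) {
  kind <- match.arg(kind)
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("CV atom groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("CV atom groups must be disjoint")
  }
  if (kind == "coordination_number") {
    if (r0 <= 0) stop("r0 must be positive")
    if (!(m > n && n > 0)) stop("switch exponents must satisfy m > n > 0")
  }
  structure(list(kind = kind, group_a = group_a, group_b = group_b,
                 r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "cv_spec")
}

# rational switching function s(r) = (1-(r/r0)^n)/(1-(r/r0)^m); the removable
# singularity at r = r0 evaluates to n/m
switch_fn <- function(r, r0, n, m) {
  u <- r / r0
  s <- numeric(length(u))
  at_r0 <- abs(u - 1) < 1e-9
  s[at_r0] <- n / m
  uu <- u[!at_r0]
  s[!at_r0] <- (1 - uu^n) / (1 - uu^m)
  s
}

# d s / d r (same removable singularity; limit n(n-m)/(2m) / r0)
switch_fn_deriv <- function(r, r0, n, m) {
  u <- r / r0
  d <- numeric(length(u))
  at_r0 <- abs(u - 1) < 1e-9
  d[at_r0] <- n * (n - m) / (2 * m) / r0
  uu <- u[!at_r0]
  d[!at_r0] <- (-n * uu^(n - 1) * (1 - uu^m) +
                  m * uu^(m - 1) * (1 - uu^n)) / (1 - uu^m)^2 / r0
  d
}

#' Coordination number between two atom groups
#'
#' Sum over cross-group pairs of the rational switch
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`; fully formed contacts contribute
#' ~1, broken ones ~0, and a pair exactly at `r0` contributes `n/m`.
#'
#' @param frame `n_atoms x 3` coordinates (Angstrom).
#' @param spec a [cv_spec()] of kind `coordination_number`.
#' @return unitless coordination number.
#' @export
coordination_number <- function(frame, spec) {
  if (spec$kind != "coordination_number") {
    stop("spec is not a coordination_number CV")
  }
  a <- frame[spec$group_a, , drop = FALSE]
  b <- frame[spec$group_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  r <- sqrt(pmax(d2, 0))
  sum(switch_fn(r, spec$r0, spec$n, spec$m))
}

#' Centre-of-mass distance between two atom groups
#'
#' Euclidean distance of the mass-weighted centroids, reported in nm (the
#' conventional unit of the dissociation CV; coordinates are Angstrom).
#'
#' @param frame `n_atoms x 3` coordinates (Angstrom).
#' @param masses per-atom masses (positive for the atoms used).
#' @param spec a [cv_spec()] of kind `com_distance`.
#' @return distance in nm.
#' @export
com_distance <- function(frame, masses, spec) {
  if (spec$kind != "com_distance") stop("spec is not a com_distance CV")
  ma <- masses[spec$group_a]; mb <- masses[spec$group_b]
  if (sum(ma) <= 0 || sum(mb) <= 0) stop("group masses must be positive")
  ca <- colSums(frame[spec$group_a, , drop = FALSE] * ma) / sum(ma)
  cb <- colSums(frame[spec$group_b, , drop = FALSE] * mb) / sum(mb)
  sqrt(sum((ca - cb)^2)) / 10
}

#' Gaussian hill set
#'
#' @param centers matrix (n_hills x n_cv) of hill centres in CV units.
#' @param widths per-CV Gaussian sigmas (recycled to a matrix).
#' @param height hill height(s), kJ/mol.
#' @param deposit_step integration step of each deposit.
#' @return a `hill_set` tibble with columns `step`, `center_1[, center_2]`,
#'   `sigma_1[, sigma_2]`, `height`.
#' @export
hill_set <- function(centers, widths, height, deposit_step = NULL) {
  centers <- rbind(centers)
  ncv <- ncol(centers)
  widths <- matrix(rep_len(as.numeric(widths), ncv), max(nrow(centers), 1),
                   ncv, byrow = TRUE)[seq_len(nrow(centers)), , drop = FALSE]
  if (any(widths <= 0)) stop("hill widths must be positive")
  if (any(height <= 0)) stop("hill height must be positive")
  if (is.null(deposit_step)) deposit_step <- seq_len(nrow(centers))
  out <- tibble::tibble(step = as.integer(deposit_step))
  for (k in seq_len(ncv)) out[[paste0("center_", k)]] <- centers[, k]
  for (k in seq_len(ncv)) out[[paste0("sigma_", k)]] <- widths[, k]
  out$height <- rep_len(as.numeric(height), nrow(centers))
  class(out) <- unique(c("hill_set", class(out)))
  out
}

n_cv <- function(hills) sum(grepl("^center_", names(hills)))

#' Append one hill to a hill set
#'
#' The metadynamics engine calls this at every deposition pace; exposed so the
#' bias bookkeeping is testable in isolation.
#'
#' @param hills a `hill_set` (or `NULL` to start one).
#' @param cv_values current CV values (hill centre).
#' @param widths,height hill geometry (kJ/mol height).
#' @param step integration step of the deposit.
#' @return the grown `hill_set`.
#' @export
deposit_hill <- function(hills, cv_values, widths, height, step = NA_integer_) {
  new <- hill_set(matrix(cv_values, nrow = 1), widths, height,
                  deposit_step = if (is.na(step)) 1L else as.integer(step))
  if (is.null(hills)) return(new)
  out <- dplyr::bind_rows(hills, new)
  class(out) <- unique(c("hill_set", class(out)))
  out
}

#' Evaluate the accumulated bias at CV points
#'
#' `V(s) = sum_hills h * exp(-sum_cv (s_cv - c_cv)^2 / (2 sigma_cv^2))`.
#'
#' @param hills a `hill_set`.
#' @param points matrix (n_points x n_cv) or vector of CV coordinates.
#' @return bias in kJ/mol at each point.
#' @export
bias_potential <- function(hills, points) {
  ncv <- n_cv(hills)
  pts <- rbind(points)
  if (ncol(pts) != ncv) stop("points must have ", ncv, " CV column(s)")
  v <- numeric(nrow(pts))
  if (nrow(hills) == 0) return(v)
  for (k in seq_len(ncv)) {
    dk <- outer(pts[, k], hills[[paste0("center_", k)]], "-") /
      rep(hills[[paste0("sigma_", k)]], each = nrow(pts))
    v_k <- dk^2 / 2
    if (k == 1) expo <- v_k else expo <- expo + v_k
  }
  as.numeric(exp(-expo) %*% hills$height)
}

#' One-sided harmonic wall
#'
#' Restrains a CV below `position`: zero below, `kappa * (s - s0)^2` with
#' gradient `2 kappa (s - s0)` above. Used to cap the centre-of-mass distance
#' (e.g. at 3.5 nm) so the dissociated ligand does not wander off.
#'
#' @param cv_value CV value(s).
#' @param position wall position `s0` (CV units).
#' @param kappa force constant, kJ/mol per CV unit^2 (default 1000).
#' @return list with `energy` (kJ/mol) and `gradient`.
#' @export
harmonic_wall_force <- function(cv_value, position, kappa = 1000) {
  over <- pmax(cv_value - position, 0)
  list(energy = kappa * over^2, gradient = 2 * kappa * over)
}

#' Metadynamics run configuration
#'
#' Standard (fixed-height) metadynamics: constant-height Gaussian hills at a
#' fixed deposition pace. The reference setup for ligand dissociation uses
#' 0.6 kJ/mol hills every 4 ps at 310 K with a harmonic wall on CV2 at 3.5 nm;
#' those values are the defaults here (with the pace expressed in integration
#' steps).
#'
#' @param hill_height kJ/mol.
#' @param hill_widths per-CV sigmas, CV units.
#' @param pace steps between deposits (>= 1).
#' @param temperature Kelvin.
#' @param total_steps integration steps.
#' @param dt time step, ps.
#' @param friction Langevin friction, 1/ps.
#' @param mass particle mass (kJ/mol ps^2 / CV-unit^2 scale).
#' @param wall `NULL` or list `(cv_index, position, kappa)`.
#' @param grid list per CV of `(min, max, n)` for the engine's bias grid.
#' @param x0 initial CV coordinates.
#' @param seed integer seed driving the thermostat noise.
#' @return an `mtd_config` list.
#' @export
mtd_config <- function(hill_height = 0.6, hill_widths, pace,
                       temperature = 310, total_steps, dt = 0.005,
                       friction = 5, mass = 1, wall = NULL, grid, x0,
                       seed = 1L) {
  stopifnot(pace >= 1, hill_height > 0, all(hill_widths > 0), dt > 0,
            total_steps >= 1)
  if (!is.null(wall)) {
    g <- grid[[wall$cv_index]]
    if (wall$position < g$min || wall$position > g$max) {
      stop("wall position must lie within the CV grid domain")
    }
    if (is.null(wall$kappa)) wall$kappa <- 1000
  }
  structure(list(hill_height = hill_height, hill_widths = hill_widths,
                 pace = as.integer(pace), temperature = temperature,
                 total_steps = as.integer(total_steps), dt = dt,
                 friction = friction, mass = mass, wall = wall, grid = grid,
                 x0 = x0, seed = as.integer(seed)),
            class = "mtd_config")
}

#' Run standard metadynamics with Langevin dynamics on a toy potential
#'
#' BAOAB Langevin integration on a direct-CV analytic potential (the CVs are
#' the coordinates themselves), with fixed-height Gaussian hills deposited
#' every `config$pace` steps, an optional one-sided harmonic wall, and bias
#' forces taken from a grid accumulated hill-by-hill (compiled core). Runs are
#' bit-reproducible for a given config and seed.
#'
#' @param potential a toy potential from [make_toy_potential()] (kinds
#'   `harmonic`, `double_well_1d`, `two_channel_2d`).
#' @param config an [mtd_config()].
#' @param cv_stride store CV values every this many steps.
#' @return an `mtd_run`: list with `hills` (a `hill_set`), `cv_traj` (tibble),
#'   `config`, and the engine's final bias grid.
#' @export
run_langevin_mtd <- function(potential, config, cv_stride = 10L) {
  dim <- potential$dim
  stopifnot(length(config$x0) == dim, length(config$hill_widths) == dim,
            length(config$grid) == dim)
  kT <- KB_KJ_MOL_K * config$temperature
  set.seed(config$seed)
  noise <- matrix(stats::rnorm(config$total_steps * dim),
                  config$total_steps, dim)
  gmin <- vapply(config$grid, `[[`, numeric(1), "min")
  gmax <- vapply(config$grid, `[[`, numeric(1), "max")
  gn <- vapply(config$grid, function(g) as.integer(g$n), integer(1))
  wall_idx <- if (is.null(config$wall)) -1L else as.integer(config$wall$cv_index)
  wall_pos <- if (is.null(config$wall)) 0 else config$wall$position
  wall_kappa <- if (is.null(config$wall)) 0 else config$wall$kappa
  res <- mtd_engine_cpp(
    kind = potential$kind_code, params = potential$params,
    x0 = as.numeric(config$x0), nsteps = config$total_steps,
    dt = config$dt, friction = config$friction, mass = config$mass,
    kT = kT, pace = config$pace, hill_height = config$hill_height,
    hill_sigma = as.numeric(config$hill_widths),
    grid_min = gmin, grid_max = gmax, grid_n = gn,
    wall_idx = wall_idx, wall_pos = wall_pos, wall_kappa = wall_kappa,
    noise = noise, cv_stride = as.integer(cv_stride)
  )
  hills <- if (nrow(res$hill_centers) > 0) {
    hill_set(res$hill_centers, config$hill_widths, config$hill_height,
             deposit_step = as.integer(res$hill_steps))
  } else {
    hill_set(matrix(numeric(0), 0, dim), config$hill_widths,
             config$hill_height, deposit_step = integer(0))[0, ]
  }
  cv <- tibble::as_tibble(as.data.frame(res$cv_traj))
  names(cv) <- paste0("cv", seq_len(dim))
  cv$step <- res$cv_steps
  structure(list(hills = hills, cv_traj = cv, config = config,
                 bias_grid = res$bias_grid, grid = config$grid),
            class = "mtd_run")
}

#' Reconstruct a free-energy surface from deposited hills
#'
#' Standard-metadynamics estimator: the FES is the negated accumulated bias of
#' the final hill set, shifted so its minimum over the grid is zero.
#'
#' @param hills a non-empty `hill_set`.
#' @param grid list per CV of `(min, max, n)` defining a regular lattice. A
#'   sensible resolution is half the hill sigma per CV.
#' @return a `free_energy_surface`: list with `values` (kJ/mol, min 0; vector
#'   for 1 CV, matrix for 2), `axes` (grid coordinates per CV), `grid`.
#' @export
reconstruct_fes <- function(hills, grid) {
  if (is.null(hills) || nrow(hills) == 0) {
    stop("cannot reconstruct a FES from an empty hill list")
  }
  ncv <- n_cv(hills)
  stopifnot(length(grid) == ncv)
  axes <- lapply(grid, function(g) seq(g$min, g$max, length.out = g$n))
  if (ncv == 1) {
    pts <- matrix(axes[[1]], ncol = 1)
  } else {
    pts <- as.matrix(expand.grid(axes[[1]], axes[[2]]))
  }
  v <- -bias_potential(hills, pts)
  v <- v - min(v)
  values <- if (ncv == 1) as.numeric(v) else matrix(v, length(axes[[1]]),
                                                    length(axes[[2]]))
  structure(list(values = values, axes = axes, grid = grid),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- vapply(x$axes, length, integer(1))
  cat("<free_energy_surface> ", paste(dims, collapse = " x "),
      " grid, range 0 - ", round(max(x$values), 3), " kJ/mol\n", sep = "")
  invisible(x)
}

fes_cell_index <- function(fes) {
  dims <- vapply(fes$axes, length, integer(1))
  if (length(dims) == 1) {
    tibble::tibble(cell = seq_len(dims), i = seq_len(dims),
                   x = fes$axes[[1]], value = as.numeric(fes$values))
  } else {
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]))
    tibble::tibble(cell = seq_len(nrow(g)), i = g$i, j = g$j,
                   x = fes$axes[[1]][g$i], y = fes$axes[[2]][g$j],
                   value = as.numeric(fes$values))
  }
}

region_cells <- function(fes, region) {
  tab <- fes_cell_index(fes)
  keep <- tab$x >= region[[1]][1] & tab$x <= region[[1]][2]
  if (length(fes$axes) == 2) {
    keep <- keep & tab$y >= region[[2]][1] & tab$y <= region[[2]][2]
  }
  tab$cell[keep]
}

#' Dissociation barrier from a free-energy surface
#'
#' The barrier is the lowest-saddle (minimax) path value between the two
#' basins: over all grid paths from the bound-basin minimum to the
#' unbound-basin minimum, the minimum of the maximum FES value along the path,
#' minus the bound-basin minimum. Computed exactly on the grid by a union-find
#' sweep over cells in increasing FES order (4-neighbour connectivity).
#'
#' @param fes a `free_energy_surface` (1 or 2 CVs).
#' @param bound_region,unbound_region per-CV inclusive ranges, e.g.
#'   `list(c(-1.4, -0.6))` or `list(c(0, 0.5), c(2.5, 3.5))`. Must not overlap.
#' @return barrier in kcal/mol (attribute `kJ_mol` keeps the raw value).
#' @export
estimate_barrier <- function(fes, bound_region, unbound_region) {
  bcells <- region_cells(fes, bound_region)
  ucells <- region_cells(fes, unbound_region)
  if (length(bcells) == 0 || length(ucells) == 0) {
    stop("both basin regions must contain grid cells")
  }
  if (length(intersect(bcells, ucells)) > 0) {
    stop("bound and unbound regions overlap")
  }
  vals <- as.numeric(fes$values)
  bmin_cell <- bcells[which.min(vals[bcells])]
  umin_cell <- ucells[which.min(vals[ucells])]
  saddle <- minimax_saddle(fes, bmin_cell, umin_cell)
  barrier_kj <- saddle - vals[bmin_cell]
  out <- convert_energy(barrier_kj, "kJ/mol", "kcal/mol")
  attr(out, "kJ_mol") <- barrier_kj
  out
}

# exact minimax (widest-bottleneck) saddle between two cells via Kruskal-style
# union-find over cells sorted by FES value
minimax_saddle <- function(fes, cell_a, cell_b) {
  dims <- vapply(fes$axes, length, integer(1))
  vals <- as.numeric(fes$values)
  ncell <- length(vals)
  parent <- seq_len(ncell)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ord <- order(vals)
  added <- logical(ncell)
  if (length(dims) == 1) {
    neighbors <- function(c) c(if (c > 1) c - 1L, if (c < ncell) c + 1L)
  } else {
    ni <- dims[1]
    neighbors <- function(c) {
      i <- ((c - 1L) %% ni) + 1L
      j <- ((c - 1L) %/% ni) + 1L
      out <- integer(0)
      if (i > 1) out <- c(out, c - 1L)
      if (i < ni) out <- c(out, c + 1L)
      if (j > 1) out <- c(out, c - ni)
      if (j < dims[2]) out <- c(out, c + ni)
      out
    }
  }
  for (c in ord) {
    added[c] <- TRUE
    for (nb in neighbors(c)) {
      if (added[nb]) {
        ra <- find(c); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (find(cell_a) == find(cell_b) && added[cell_a] && added[cell_b]) {
      return(vals[c])
    }
  }
  stop("basins are not connected on the grid")
}

#' Combine dissociation barriers from replica runs
#'
#' Replica metadynamics runs started from different frames give independent
#' barrier estimates; the reported uncertainty is their sample standard
#' deviation (undefined for a single replica).
#'
#' @param barriers numeric vector of per-replica barriers, kcal/mol.
#' @return a `barrier_estimate`: list with `per_replica`, `mean`, `sd`
#'   (`NA` for one replica), `n`.
#' @export
aggregate_replicas <- function(barriers) {
  barriers <- as.numeric(barriers)
  if (length(barriers) == 0) stop("no replica barriers supplied")
  structure(list(per_replica = barriers, mean = mean(barriers),
                 sd = if (length(barriers) >= 2) stats::sd(barriers) else NA_real_,
                 n = length(barriers)),
            class = "barrier_estimate")
}

#' @export
print.barrier_estimate <- function(x, ...) {
  cat("<barrier_estimate> ", format(round(x$mean, 2)),
      if (!is.na(x$sd)) paste0(" +/- ", format(round(x$sd, 2))),
      " kcal/mol (", x$n, " replica", if (x$n > 1) "s", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.barrier_estimate <- function(x, ...) {
  tibble::tibble(replica = seq_len(x$n), barrier = x$per_replica)
}

#' @export
glance.barrier_estimate <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n)
}
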