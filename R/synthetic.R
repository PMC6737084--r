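#' Synthetic block-correlated C-alpha trajectory
#'
#' Emulates the statistical structure the covariance / cross-correlation
#' analysis estimates: one C-alpha per residue on a rigid extended backbone
#' (3.8 Angstrom spacing along x), plus zero-mean Gaussian displacements whose
#' residue-residue correlation matrix has `within_block_rho` inside each
#' segment and `cross_block_rho` between the named segment pairs (0
#' elsewhere). The same scalar correlation structure is sampled independently
#' for x, y and z, so the dot-product covariance between residues i and j is
#' `3 sigma^2 rho_ij` and the target Pearson cross-correlation is exactly
#' `rho_ij` — returned as `true_cc` for parameter-recovery tests.
#'
#' The implied correlation matrix is validated positive semi-definite
#' (eigenvalue floor −1e-10) before sampling; a non-PSD specification fails
#' loudly rather than being silently repaired.
#'
#' @param segments a `segment_map` (consecutive residue ranges on one chain).
#' @param within_block_rho correlation between residues of the same segment,
#'   in (−1, 1).
#' @param cross_block_rho named list of segment-pair correlations, names like
#'   `"H3:H12"`.
#' @param n_frames number of frames.
#' @param noise_sd per-coordinate displacement standard deviation, Angstrom.
#' @param seed integer seed.
#' @return list with `trajectory`, `true_cc` (residue x residue), `topology`,
#'   `segments`.
#' @export
generate_correlated_trajectory <- function(segments, within_block_rho = 0,
                                           cross_block_rho = list(),
                                           n_frames = 1000, noise_sd = 0.5,
                                           seed = 1) {
  res_tbl <- purrr::map_dfr(segments$segment_name, function(nm) {
    r <- segment_residues(segments, nm)
    r$segment <- nm
    r
  })
  nres <- nrow(res_tbl)
  rho <- diag(nres)
  same_seg <- outer(res_tbl$segment, res_tbl$segment, "==")
  rho[same_seg & !diag(nres)] <- within_block_rho
  for (key in names(cross_block_rho)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% segments$segment_name)) {
      stop("cross_block_rho names must be 'segA:segB' with known segments: ",
           key)
    }
    ia <- res_tbl$segment == pair[1]
    ib <- res_tbl$segment == pair[2]
    rho[ia, ib] <- cross_block_rho[[key]]
    rho[ib, ia] <- cross_block_rho[[key]]
  }
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    stop("implied correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev$values), 3), ")")
  }
  sqrt_rho <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  top <- make_topology(atom_name = "CA",
                       residue_index = res_tbl$residue_index,
                       residue_name = "ALA",
                       chain_id = res_tbl$chain_id, element = "C")
  base <- cbind(3.8 * seq_len(nres), 0, 0)
  set.seed(seed)
  coords <- array(0, dim = c(n_frames, nres, 3))
  for (d in 1:3) {
    z <- matrix(stats::rnorm(n_frames * nres), n_frames, nres)
    coords[, , d] <- sweep(noise_sd * z %*% sqrt_rho, 2, base[, d], "+")
  }
  list(trajectory = new_trajectory(top, coords), true_cc = rho,
       topology = top, segments = segments)
}

#' Synthetic donor/H/acceptor system with designed H-bond occupancy
#'
#' One donor (with one covalent hydrogen) and one acceptor. In exactly
#' `round(bonded_frame_fraction * n_frames)` frames (a seeded random subset)
#' the acceptor sits well inside the geometric criteria (collinear D–H...A at
#' 80% of the distance cutoff); in the rest it sits far outside. Ground truth
#' is returned alongside the trajectory.
#'
#' @param n_frames number of frames.
#' @param bonded_frame_fraction fraction in \[0, 1\].
#' @param criteria an [hbond_criteria()].
#' @param seed integer seed.
#' @return list with `trajectory`, `bonded_frames` (logical), `occupancy`
#'   (the designed fraction), `donor_id`, `hydrogen_id`, `acceptor_id`.
#' @export
generate_hbond_system <- function(n_frames = 100, bonded_frame_fraction = 0.5,
                                  criteria = hbond_criteria(), seed = 1) {
  stopifnot(bonded_frame_fraction >= 0, bonded_frame_fraction <= 1)
  top <- make_topology(atom_name = c("NZ", "HZ1", "OE1"),
                       residue_index = c(1L, 1L, 2L),
                       residue_name = c("LYS", "LYS", "GLU"),
                       element = c("N", "H", "O"))
  n_bonded <- round(bonded_frame_fraction * n_frames)
  set.seed(seed)
  bonded <- rep(FALSE, n_frames)
  bonded[sample.int(n_frames, n_bonded)] <- TRUE
  near <- 0.8 * criteria$max_da_distance
  far <- 3 * criteria$max_da_distance
  coords <- array(0, dim = c(n_frames, 3, 3))
  coords[, 2, 1] <- 1.0                              # H on the x axis
  coords[, 3, 1] <- ifelse(bonded, near, far)        # acceptor, collinear
  list(trajectory = new_trajectory(top, coords), bonded_frames = bonded,
       occupancy = n_bonded / n_frames,
       donor_id = 1L, hydrogen_id = 2L, acceptor_id = 3L)
}

#' Synthetic compound descriptor table with designed filter pass rates
#'
#' For each rule (MW, HBD, HBA, logP, rotatable bonds) exactly
#' `round((1 - pass_fraction) * n)` compounds are sampled (seeded, possibly
#' overlapping across rules) to violate it; descriptor values are then drawn
#' from ranges strictly inside or strictly outside the rule threshold. Ground
#' truth per compound and per rule is returned.
#'
#' @param n number of compounds.
#' @param pass_fraction_per_rule named list/vector with entries `mw`, `hbd`,
#'   `hba`, `logp`, `rot`, each in \[0, 1\] (defaults 1: everything passes).
#' @param seed integer seed.
#' @return list with `compounds` (tibble: `compound_id`, `mw`, `hbd`, `hba`,
#'   `logp`, `rotatable_bonds`, `heavy_atom_count`) and `truth` (per-rule
#'   logical pass columns plus `passes_all` and `first_failing_rule`).
#' @export
generate_compound_table <- function(n = 1000,
                                    pass_fraction_per_rule = list(),
                                    seed = 1) {
  frac <- utils::modifyList(
    list(mw = 1, hbd = 1, hba = 1, logp = 1, rot = 1),
    as.list(pass_fraction_per_rule))
  stopifnot(all(unlist(frac) >= 0), all(unlist(frac) <= 1))
  set.seed(seed)
  violate <- function(f) {
    v <- rep(FALSE, n)
    v[sample.int(n, round((1 - f) * n))] <- TRUE
    v
  }
  v_mw <- violate(frac$mw); v_hbd <- violate(frac$hbd)
  v_hba <- violate(frac$hba); v_logp <- violate(frac$logp)
  v_rot <- violate(frac$rot)
  compounds <- tibble::tibble(
    compound_id = sprintf("CMP%05d", seq_len(n)),
    mw = ifelse(v_mw, stats::runif(n, 510, 900), stats::runif(n, 150, 490)),
    hbd = ifelse(v_hbd, sample(6:10, n, TRUE), sample(0:5, n, TRUE)),
    hba = ifelse(v_hba, sample(11:16, n, TRUE), sample(0:10, n, TRUE)),
    logp = ifelse(v_logp, stats::runif(n, 5.1, 9), stats::runif(n, -2, 4.9)),
    rotatable_bonds = ifelse(v_rot, sample(11:20, n, TRUE),
                             sample(0:10, n, TRUE)),
    heavy_atom_count = sample(10:40, n, TRUE)
  )
  rules <- c("MW", "HBD", "HBA", "LOGP", "ROT")
  viol <- cbind(MW = v_mw, HBD = v_hbd, HBA = v_hba, LOGP = v_logp,
                ROT = v_rot)
  first_fail <- apply(viol, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_character_ else rules[w[1]]
  })
  truth <- tibble::tibble(
    compound_id = compounds$compound_id,
    passes_mw = !v_mw, passes_hbd = !v_hbd, passes_hba = !v_hba,
    passes_logp = !v_logp, passes_rot = !v_rot,
    passes_all = !(v_mw | v_hbd | v_hba | v_logp | v_rot),
    first_failing_rule = first_fail
  )
  list(compounds = compounds, truth = truth)
}

#' Synthetic docking-score matrix over receptor conformations
#'
#' Each compound/target cell holds a pose with probability `pose_fraction`
#' (missing cell = no favourable pose) and a uniform score in `score_range`
#' (kcal/mol). Used to exercise the consensus-selection predicates.
#'
#' @param compound_ids character vector of compound ids.
#' @param targets target structure labels; default the five mutant-receptor
#'   conformations used for consensus docking.
#' @param pose_fraction probability a pose exists.
#' @param score_range kcal/mol range for present scores.
#' @param seed integer seed.
#' @return a score tibble: `compound_id` plus one numeric column per target
#'   (NA = no pose).
#' @export
generate_score_matrix <- function(compound_ids,
                                  targets = c("Y537S_AZD", "Y537S_FULV",
                                              "Y537N_FULV", "D538G_AZD",
                                              "D538G_FULV"),
                                  pose_fraction = 0.6,
                                  score_range = c(-10, -5), seed = 1) {
  set.seed(seed)
  n <- length(compound_ids)
  out <- tibble::tibble(compound_id = compound_ids)
  for (t in targets) {
    sc <- stats::runif(n, score_range[1], score_range[2])
    sc[stats::runif(n) > pose_fraction] <- NA_real_
    out[[t]] <- sc
  }
  out
}

#' Toy energy landscapes with known barriers
#'
#' Desk-scale surrogates for the protein–ligand dissociation landscape:
#' * `harmonic` — `V = 0.5 * sum k_d x_d^2` (no barrier; thermodynamic checks).
#' * `double_well_1d` — `V = h (x^2 - 1)^2`: minima at x = ±1, analytic
#'   barrier `h` kJ/mol at x = 0.
#' * `two_channel_2d` — two basins at (±1, ±1) connected by channels at
#'   y = ±1 whose saddles at (0, ±1) have heights `h1` and `h2`; a quartic
#'   confinement `k_conf (y^2 - 1)^2` keeps paths in the channels. Analytic
#'   minimax barrier `min(h1, h2)`.
#' * `host_guest` — 4 fixed host atoms (tetrahedron) with Gaussian attractive
#'   wells binding one guest particle; CVs must be computed from coordinates
#'   (exercises the chain-rule bias-force path). No closed-form barrier.
#'
#' @param kind potential kind.
#' @param h,h1,h2 barrier parameters, kJ/mol.
#' @param k spring constant(s) for `harmonic`.
#' @param k_conf,sigma_y channel confinement and saddle width
#'   (`two_channel_2d`).
#' @param well_depth,well_width host–guest attraction (kJ/mol, Angstrom).
#' @return a `toy_potential`: list with `kind`, `dim`, `energy(x)`,
#'   `gradient(x)`, `analytic_barrier` (kJ/mol or NA), `minima`, plus
#'   engine plumbing (`kind_code`, `params`).
#' @export
make_toy_potential <- function(kind = c("double_well_1d", "two_channel_2d",
                                        "harmonic", "host_guest"),
                               h = 10, h1 = 10, h2 = 20, k = 10,
                               k_conf = 60, sigma_y = 0.3,
                               well_depth = 20, well_width = 1.5) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    k <- as.numeric(k)
    pot <- list(
      kind = kind, dim = length(k), kind_code = 1L, params = k,
      energy = function(x) 0.5 * sum(k * x^2),
      gradient = function(x) k * x,
      analytic_barrier = NA_real_, minima = list(rep(0, length(k))))
  } else if (kind == "double_well_1d") {
    stopifnot(h > 0)
    pot <- list(
      kind = kind, dim = 1L, kind_code = 2L, params = h,
      energy = function(x) h * (x[1]^2 - 1)^2,
      gradient = function(x) 4 * h * x[1] * (x[1]^2 - 1),
      analytic_barrier = h, minima = list(-1, 1))
  } else if (kind == "two_channel_2d") {
    stopifnot(h1 > 0, h2 > 0, k_conf > max(h1, h2))
    params <- c(h1, h2, k_conf, sigma_y)
    energy <- function(x) {
      q <- (1 - x[1]^2)^2
      b <- h1 * exp(-(x[2] - 1)^2 / (2 * sigma_y^2)) +
        h2 * exp(-(x[2] + 1)^2 / (2 * sigma_y^2))
      q * b + k_conf * (x[2]^2 - 1)^2
    }
    gradient <- function(x) {
      q <- (1 - x[1]^2)^2
      dq <- -4 * x[1] * (1 - x[1]^2)
      g1 <- exp(-(x[2] - 1)^2 / (2 * sigma_y^2))
      g2 <- exp(-(x[2] + 1)^2 / (2 * sigma_y^2))
      b <- h1 * g1 + h2 * g2
      db <- -h1 * g1 * (x[2] - 1) / sigma_y^2 - h2 * g2 * (x[2] + 1) / sigma_y^2
      c(dq * b, q * db + 4 * k_conf * x[2] * (x[2]^2 - 1))
    }
    pot <- list(kind = kind, dim = 2L, kind_code = 3L, params = params,
                energy = energy, gradient = gradient,
                analytic_barrier = min(h1, h2),
                minima = list(c(-1, 1), c(1, 1), c(-1, -1), c(1, -1)))
  } else {
    host <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 1.5
    energy <- function(x) {
      d2 <- rowSums(sweep(host, 2, x)^2)
      -well_depth * sum(exp(-d2 / (2 * well_width^2)))
    }
    gradient <- function(x) {
      dv <- sweep(host, 2, x)            # host - guest
      d2 <- rowSums(dv^2)
      w <- well_depth * exp(-d2 / (2 * well_width^2)) / well_width^2
      -colSums(dv * w)
    }
    pot <- list(kind = kind, dim = 3L, kind_code = NA_integer_,
                params = c(well_depth, well_width),
                energy = energy, gradient = gradient,
                analytic_barrier = NA_real_, minima = list(c(0, 0, 0)),
                host_coords = host)
  }
  class(pot) <- "toy_potential"
  pot
}
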