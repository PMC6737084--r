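# Host-guest metadynamics tier: the CVs (coordination number, COM distance)
# are functions of particle coordinates, so bias forces go through the chain
# rule dV_bias/dr = sum_cv dV_bias/dcv * dcv/dr. Only the guest particle
# moves; the host atoms are fixed. Runs are short by construction (this tier
# exists to exercise the chain-rule path, not to sample).

# gradient of the coordination number wrt the guest position (guest must be
# the sole member of group_a)
cn_gradient_guest <- function(frame, spec) {
  g <- frame[spec$group_a[1], ]
  host <- frame[spec$group_b, , drop = FALSE]
  dv <- sweep(host, 2, g, "-")          # host - guest
  r <- sqrt(rowSums(dv^2))
  ds <- switch_fn_deriv(r, spec$r0, spec$n, spec$m)
  # dr/dg = (g - host)/r
  colSums((-dv / pmax(r, 1e-12)) * ds)
}

# gradient of the COM distance (nm) wrt the guest position (Angstrom)
com_gradient_guest <- function(frame, masses, spec) {
  ma <- masses[spec$group_a]; mb <- masses[spec$group_b]
  ca <- colSums(frame[spec$group_a, , drop = FALSE] * ma) / sum(ma)
  cb <- colSums(frame[spec$group_b, , drop = FALSE] * mb) / sum(mb)
  d <- sqrt(sum((ca - cb)^2))
  if (d < 1e-12) return(c(0, 0, 0))
  (masses[spec$group_a[1]] / sum(ma)) * (ca - cb) / d / 10
}

# dV_bias/dcv at one CV point (analytic Gaussian derivatives)
bias_cv_gradient <- function(hills, cv) {
  ncv <- n_cv(hills)
  if (nrow(hills) == 0) return(numeric(ncv))
  expo <- 0
  dk <- vector("list", ncv)
  for (k in seq_len(ncv)) {
    dk[[k]] <- (cv[k] - hills[[paste0("center_", k)]]) /
      hills[[paste0("sigma_", k)]]^2
    expo <- expo + (cv[k] - hills[[paste0("center_", k)]])^2 /
      (2 * hills[[paste0("sigma_", k)]]^2)
  }
  e <- hills$height * exp(-expo)
  vapply(seq_len(ncv), function(k) -sum(e * dk[[k]]), numeric(1))
}

#' Chain-rule bias force on the guest particle
#'
#' Force contribution of the accumulated bias on the guest coordinates,
#' `-sum_cv dV_bias/dcv * dcv/dr_guest`, for the coordination-number +
#' COM-distance CV pair. Exposed so the chain rule can be validated against a
#' finite-difference oracle.
#'
#' @param hills a 2-CV `hill_set`.
#' @param frame full `n_atoms x 3` coordinates (guest + host).
#' @param cv1,cv2 the two [cv_spec()]s (coordination, COM distance).
#' @param masses per-atom masses.
#' @return length-3 force vector (kJ/mol per Angstrom).
#' @export
hostguest_bias_force <- function(hills, frame, cv1, cv2, masses) {
  cvv <- c(coordination_number(frame, cv1), com_distance(frame, masses, cv2))
  dvdcv <- bias_cv_gradient(hills, cvv)
  -(dvdcv[1] * cn_gradient_guest(frame, cv1) +
      dvdcv[2] * com_gradient_guest(frame, masses, cv2))
}

#' Metadynamics on the host-guest toy system
#'
#' BAOAB Langevin dynamics of the guest particle in the host's attractive
#' wells, biased along (coordination number, COM distance) with fixed-height
#' Gaussian hills and an optional one-sided wall on CV2. Deterministic for a
#' given seed.
#'
#' @param potential a `host_guest` [make_toy_potential()].
#' @param hill_height kJ/mol; `hill_widths` per-CV sigmas.
#' @param hill_widths,pace,temperature,total_steps,dt,friction,mass,seed
#'   integration and deposition settings (see [mtd_config()]).
#' @param wall optional list `(cv_index, position, kappa)`.
#' @param guest_start initial guest position (Angstrom).
#' @return an `mtd_run`-style list with `hills`, `cv_traj`, `guest_traj`.
#' @export
run_hostguest_mtd <- function(potential, hill_height = 0.6,
                              hill_widths = c(0.1, 0.025), pace = 25L,
                              temperature = 310, total_steps = 2000L,
                              dt = 0.002, friction = 5, mass = 1,
                              wall = list(cv_index = 2, position = 1.5,
                                          kappa = 1000),
                              guest_start = c(0, 0, 0), seed = 1) {
  stopifnot(potential$kind == "host_guest")
  host <- potential$host_coords
  n_host <- nrow(host)
  masses <- c(1, rep(12, n_host))
  cv1 <- cv_spec("coordination_number", group_a = 1L,
                 group_b = seq_len(n_host) + 1L, r0 = 3.0)
  cv2 <- cv_spec("com_distance", group_a = 1L, group_b = seq_len(n_host) + 1L)
  frame <- rbind(guest_start, host)
  kT <- KB_KJ_MOL_K * temperature
  a <- exp(-friction * dt)
  bnoise <- sqrt(kT * mass * (1 - a^2))
  set.seed(seed)
  hills <- hill_set(matrix(numeric(0), 0, 2), hill_widths, hill_height,
                    deposit_step = integer(0))
  p <- c(0, 0, 0)
  cv_rows <- vector("list", total_steps + 1)
  guest_traj <- matrix(0, total_steps + 1, 3)
  total_force <- function(fr) {
    fsys <- -potential$gradient(fr[1, ])
    fbias <- hostguest_bias_force(hills, fr, cv1, cv2, masses)
    fwall <- c(0, 0, 0)
    if (!is.null(wall)) {
      cvv <- if (wall$cv_index == 1) coordination_number(fr, cv1) else
        com_distance(fr, masses, cv2)
      w <- harmonic_wall_force(cvv, wall$position, wall$kappa)
      if (w$gradient != 0) {
        dcv <- if (wall$cv_index == 1) cn_gradient_guest(fr, cv1) else
          com_gradient_guest(fr, masses, cv2)
        fwall <- -w$gradient * dcv
      }
    }
    fsys + fbias + fwall
  }
  record <- function(i, fr) {
    cv_rows[[i]] <<- c(coordination_number(fr, cv1),
                       com_distance(fr, masses, cv2))
    guest_traj[i, ] <<- fr[1, ]
  }
  record(1, frame)
  f <- total_force(frame)
  for (s in seq_len(total_steps)) {
    p <- p + 0.5 * dt * f
    frame[1, ] <- frame[1, ] + 0.5 * dt * p / mass
    p <- a * p + bnoise * stats::rnorm(3)
    frame[1, ] <- frame[1, ] + 0.5 * dt * p / mass
    if (!all(is.finite(frame[1, ]))) stop("integration diverged at step ", s)
    if (s %% pace == 0) {
      cvv <- c(coordination_number(frame, cv1),
               com_distance(frame, masses, cv2))
      hills <- deposit_hill(hills, cvv, hill_widths, hill_height, step = s)
    }
    f <- total_force(frame)
    p <- p + 0.5 * dt * f
    record(s + 1, frame)
  }
  cv_traj <- tibble::as_tibble(do.call(rbind, cv_rows), .name_repair = "minimal")
  names(cv_traj) <- c("cv1", "cv2")
  cv_traj$step <- 0:total_steps
  structure(list(hills = hills, cv_traj = cv_traj, guest_traj = guest_traj,
                 cv1 = cv1, cv2 = cv2, masses = masses),
            class = "mtd_run")
}
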