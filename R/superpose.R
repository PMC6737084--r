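#' Least-squares RMS-fit of a trajectory onto its first frame
#'
#' Every frame is rigidly superposed (optimal rotation + translation, via
#' [bio3d::fit.xyz()]) onto frame 1 over the fit selection; the transform is
#' applied to all atoms. This removes the global rotational and translational
#' motion before covariance analysis.
#'
#' @param traj a `trajectory`.
#' @param fit_selection atom ids to fit on (>= 3 non-collinear atoms).
#' @param reference currently only `"first_frame"`.
#' @return the fitted `trajectory`.
#' @export
rms_fit_trajectory <- function(traj, fit_selection,
                               reference = c("first_frame")) {
  reference <- match.arg(reference)
  ids <- as_selection_ids(fit_selection, traj$topology)
  if (length(ids) < 3) stop("fit selection needs at least 3 atoms")
  ref <- frame_coords(traj, 1)[ids, , drop = FALSE]
  if (collinear_points(ref)) {
    stop("degenerate fit reference: selected atoms are collinear")
  }
  xyz <- traj_xyz_matrix(traj)
  inds <- as.vector(rbind(3 * ids - 2, 3 * ids - 1, 3 * ids))
  fitted <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  new_trajectory(traj$topology, xyz_matrix_to_coords(fitted), traj$times)
}

collinear_points <- function(m) {
  if (nrow(m) < 3) return(TRUE)
  c0 <- sweep(m, 2, colMeans(m))
  sv <- svd(c0, nu = 0, nv = 0)$d
  sv[2] < 1e-8 * max(sv[1], 1e-12)
}

#' RMSD between two frames
#'
#' Root-mean-square deviation over a selection, optionally after optimal
#' rigid-body superposition ([bio3d::fit.xyz()]). Full precision is kept (no
#' rounding of the deviation).
#'
#' @param frame_a,frame_b `n_atoms x 3` coordinate matrices (Angstrom).
#' @param selection atom ids to compare (default: all).
#' @param fit superpose `frame_b` onto `frame_a` first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, selection = NULL, fit = FALSE) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frames differ in shape")
  if (is.null(selection)) selection <- seq_len(nrow(frame_a))
  ids <- sort(unique(as.integer(selection)))
  if (length(ids) < 1) stop("empty selection")
  a <- frame_a[ids, , drop = FALSE]
  b <- frame_b[ids, , drop = FALSE]
  if (fit) {
    inds <- seq_len(3 * length(ids))
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(a)),
                             mobile = as.vector(t(b)),
                             fixed.inds = inds, mobile.inds = inds)
    b <- matrix(fitted, ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

# all-pairs fitted RMSD matrix over a selection (used by Daura clustering)
pairwise_rmsd <- function(traj, selection, fit = TRUE) {
  ids <- as_selection_ids(selection, traj$topology)
  nf <- n_frames(traj)
  d <- matrix(0, nf, nf)
  frames <- lapply(seq_len(nf), function(k)
    frame_coords(traj, k)[ids, , drop = FALSE])
  for (i in seq_len(nf - 1)) {
    for (j in seq((i + 1), nf)) {
      d[i, j] <- d[j, i] <- rmsd(frames[[i]], frames[[j]], fit = fit)
    }
  }
  d
}
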