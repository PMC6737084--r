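#' Geometric hydrogen-bond criteria
#'
#' Defaults are common MD practice: donor–acceptor distance <= 3.5 Angstrom
#' and donor–H–acceptor angle >= 120 degrees. Every occupancy table records
#' the criteria it was computed with.
#'
#' @param max_da_distance maximum donor–acceptor distance, Angstrom (> 0).
#' @param min_dha_angle minimum donor–H–acceptor angle, degrees, in (0, 180].
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120) {
  stopifnot(max_da_distance > 0, min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle), class = "hbond_criteria")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every donor heavy atom, its covalently attached hydrogens are found
#' (bonded hydrogen = within 1.2 Angstrom in frame 1 when no bond records are
#' available). A donor–H–acceptor triple counts as bonded in a frame iff the
#' donor–acceptor distance is at most `criteria$max_da_distance` and the angle
#' at the hydrogen is at least `criteria$min_dha_angle`. Occupancy is the
#' fraction of frames bonded; this is the persistence statistic behind calling
#' an interaction a persistent anchor (e.g. the L346 / E419 / K529 contacts of
#' antiestrogens in the ligand-binding cavity) versus a transient one.
#'
#' @param traj a `trajectory` whose topology includes hydrogens.
#' @param donors selection of donor heavy atoms.
#' @param acceptors selection of acceptor heavy atoms.
#' @param criteria an [hbond_criteria()].
#' @param report_floor drop triples with occupancy below this (default 0:
#'   report every triple ever bonded).
#' @return an `hbond_table` tibble: `donor_atom`, `hydrogen_atom`,
#'   `acceptor_atom` (labels `chain:resname resno:name`), the three atom ids,
#'   `occupancy`, `mean_distance` (mean donor–acceptor distance over bonded
#'   frames, Angstrom); attribute `criteria`.
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria(), report_floor = 0) {
  top <- traj$topology
  don <- as_selection_ids(donors, top)
  acc <- as_selection_ids(acceptors, top)
  don <- don[!top$is_hydrogen[don]]
  acc <- acc[!top$is_hydrogen[acc]]
  if (length(don) == 0 || length(acc) == 0) {
    stop("donor and acceptor selections must contain heavy atoms")
  }
  hyd <- top$atom_id[top$is_hydrogen]
  f1 <- frame_coords(traj, 1)
  triples <- purrr::map_dfr(don, function(d) {
    att <- if (length(hyd) == 0) integer(0) else {
      dist_h <- sqrt(colSums((t(f1[hyd, , drop = FALSE]) - f1[d, ])^2))
      hyd[dist_h <= 1.2]
    }
    if (length(att) == 0) {
      warning("donor atom ", d, " has no covalent hydrogen; skipped")
      return(tibble::tibble())
    }
    tidyr::expand_grid(donor = d, hydrogen = att,
                       acceptor = setdiff(acc, d))
  })
  if (nrow(triples) == 0) {
    return(empty_hbond_table(criteria))
  }
  nf <- n_frames(traj)
  res <- purrr::pmap_dfr(triples, function(donor, hydrogen, acceptor) {
    dvec <- traj$coords[, donor, ] - traj$coords[, acceptor, ]
    if (nf == 1) dim(dvec) <- c(1, 3)
    da <- sqrt(rowSums(dvec^2))
    hd <- traj$coords[, donor, ] - traj$coords[, hydrogen, ]
    ha <- traj$coords[, acceptor, ] - traj$coords[, hydrogen, ]
    if (nf == 1) { dim(hd) <- c(1, 3); dim(ha) <- c(1, 3) }
    cosang <- rowSums(hd * ha) /
      pmax(sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)), 1e-12)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    bonded <- da <= criteria$max_da_distance & ang >= criteria$min_dha_angle
    tibble::tibble(donor_id = donor, hydrogen_id = hydrogen,
                   acceptor_id = acceptor,
                   occupancy = mean(bonded),
                   mean_distance = if (any(bonded)) mean(da[bonded]) else NA_real_)
  })
  res <- res[res$occupancy > 0 & res$occupancy >= report_floor, , drop = FALSE]
  out <- tibble::tibble(
    donor_atom = atom_label(top, res$donor_id),
    hydrogen_atom = atom_label(top, res$hydrogen_id),
    acceptor_atom = atom_label(top, res$acceptor_id),
    donor_id = res$donor_id, hydrogen_id = res$hydrogen_id,
    acceptor_id = res$acceptor_id,
    occupancy = res$occupancy, mean_distance = res$mean_distance
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$occupancy))
  attr(out, "criteria") <- criteria
  class(out) <- unique(c("hbond_table", class(out)))
  out
}

empty_hbond_table <- function(criteria) {
  out <- tibble::tibble(donor_atom = character(), hydrogen_atom = character(),
                        acceptor_atom = character(), donor_id = integer(),
                        hydrogen_id = integer(), acceptor_id = integer(),
                        occupancy = numeric(), mean_distance = numeric())
  attr(out, "criteria") <- criteria
  class(out) <- unique(c("hbond_table", class(out)))
  out
}

atom_label <- function(top, ids) {
  i <- match(ids, top$atom_id)
  paste0(top$chain_id[i], ":", top$residue_name[i], top$residue_index[i],
         ":", top$atom_name[i])
}
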