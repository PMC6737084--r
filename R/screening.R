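#' Lipinski + rotatable-bond property filter
#'
#' Keeps compounds with MW <= 500 Da, H-bond donors <= 5, acceptors <= 10,
#' logP <= 5 (Lipinski's rule of five as a hard conjunctive filter — the aim
#' is to drop poor-absorption compounds, so no "one violation allowed"
#' variant by default) and at most `max_rotatable` rotatable bonds (high
#' flexibility costs entropy and oral availability). Each rejection is
#' attributed to the first failing rule in the order MW, HBD, HBA, LOGP, ROT.
#'
#' @param compounds tibble with columns `compound_id`, `mw`, `hbd`, `hba`,
#'   `logp`, `rotatable_bonds` (no missing values allowed).
#' @param max_rotatable rotatable-bond cap (default 10).
#' @param max_mw,max_hbd,max_hba,max_logp Lipinski thresholds.
#' @param allow_one_violation Lipinski variant: pass with at most one of the
#'   four rules violated (the rotatable-bond rule always applies).
#' @return a `filter_result`: list with `passed` (tibble of surviving rows),
#'   `rejected` (tibble `compound_id`, `first_failing_rule`), `tally` (tibble
#'   `rule`, `n_rejected`).
#' @export
property_filter <- function(compounds, max_rotatable = 10, max_mw = 500,
                            max_hbd = 5, max_hba = 10, max_logp = 5,
                            allow_one_violation = FALSE) {
  need <- c("compound_id", "mw", "hbd", "hba", "logp", "rotatable_bonds")
  miss <- setdiff(need, names(compounds))
  if (length(miss) > 0) stop("missing descriptor column(s): ",
                             paste(miss, collapse = ", "))
  bad <- compounds$compound_id[!stats::complete.cases(
    compounds[, c("mw", "hbd", "hba", "logp", "rotatable_bonds")])]
  if (length(bad) > 0) {
    stop("missing descriptor value(s) for compound(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  }
  fails <- cbind(MW = compounds$mw > max_mw,
                 HBD = compounds$hbd > max_hbd,
                 HBA = compounds$hba > max_hba,
                 LOGP = compounds$logp > max_logp,
                 ROT = compounds$rotatable_bonds > max_rotatable)
  if (allow_one_violation) {
    lip_reject <- rowSums(fails[, 1:4, drop = FALSE]) > 1
  } else {
    lip_reject <- rowSums(fails[, 1:4, drop = FALSE]) > 0
  }
  reject <- lip_reject | fails[, "ROT"]
  rules <- colnames(fails)
  first_fail <- rep(NA_character_, nrow(compounds))
  first_fail[reject] <- apply(fails[reject, , drop = FALSE], 1, function(r)
    rules[which(r)[1]])
  tally <- tibble::tibble(rule = rules,
                          n_rejected = vapply(rules, function(r)
                            sum(first_fail == r, na.rm = TRUE), integer(1),
                            USE.NAMES = FALSE))
  structure(list(
    passed = compounds[!reject, , drop = FALSE],
    rejected = tibble::tibble(compound_id = compounds$compound_id[reject],
                              first_failing_rule = first_fail[reject]),
    tally = tally
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  n_in <- nrow(x$passed) + nrow(x$rejected)
  cat("<filter_result> ", nrow(x$passed), "/", n_in, " compounds pass\n",
      sep = "")
  print(x$tally)
  invisible(x)
}

#' @export
glance.filter_result <- function(x, ...) {
  tibble::tibble(n_input = nrow(x$passed) + nrow(x$rejected),
                 n_passed = nrow(x$passed), n_rejected = nrow(x$rejected))
}

score_columns <- function(scores) {
  setdiff(names(scores), "compound_id")
}

# shared consensus worker; docking scores are negative, "lower than cutoff"
# is applied as <= (a strict-mode flag is available)
consensus_select <- function(scores, cutoff, min_targets, protocol,
                             strict = FALSE) {
  targets <- score_columns(scores)
  if (length(targets) < 1 || nrow(scores) == 0) {
    stop("score matrix must have at least one target column and one compound")
  }
  m <- as.matrix(scores[, targets])
  if (any(is.infinite(m), na.rm = TRUE)) stop("scores must be finite")
  best <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  best[is.infinite(best)] <- NA_real_
  n_pose <- rowSums(!is.na(m))
  within <- !is.na(best) & (if (strict) best < cutoff else best <= cutoff)
  selected <- within & n_pose >= min_targets
  best_target <- targets[apply(m, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))]
  out <- tibble::tibble(
    compound_id = scores$compound_id[selected],
    best_score = best[selected],
    best_target = best_target[selected],
    n_targets_with_pose = n_pose[selected],
    triggering_targets = vapply(which(selected), function(i)
      paste(targets[!is.na(m[i, ]) &
                      (if (strict) m[i, ] < cutoff else m[i, ] <= cutoff)],
            collapse = ","), character(1))
  )
  # re-validation pass: every selected compound must satisfy the predicate
  ok <- vapply(seq_len(nrow(out)), function(i) {
    r <- m[match(out$compound_id[i], scores$compound_id), ]
    sum(!is.na(r)) >= min_targets &&
      (if (strict) min(r, na.rm = TRUE) < cutoff
       else min(r, na.rm = TRUE) <= cutoff)
  }, logical(1))
  if (!all(ok)) stop("internal error: selection failed predicate re-check")
  attr(out, "protocol") <- protocol
  attr(out, "cutoff") <- cutoff
  attr(out, "min_targets") <- min_targets
  class(out) <- unique(c("selection_report", class(out)))
  out
}

#' Structure-based consensus selection
#'
#' Protocol for docking-funnel hits: select a compound iff it has a favourable
#' pose (a present score) on at least one target conformation with docking
#' score at or below `cutoff` (default −8.5 kcal/mol).
#'
#' @param scores tibble `compound_id` + one numeric column per target
#'   conformation; NA = no favourable pose.
#' @param cutoff kcal/mol.
#' @param strict use strictly-below comparison instead of <=.
#' @return a `selection_report` tibble (attributes `protocol`, `cutoff`).
#' @export
consensus_select_structure_based <- function(scores, cutoff = -8.5,
                                             strict = FALSE) {
  consensus_select(scores, cutoff, min_targets = 1L,
                   protocol = "structure_based", strict = strict)
}

#' Ligand-based consensus selection
#'
#' Protocol for scaffold-derived candidates: select a compound iff it shows
#' favourable poses on at least two distinct target conformations and at
#' least one of its scores is at or below `cutoff` (default −7.5 kcal/mol).
#'
#' @inheritParams consensus_select_structure_based
#' @export
consensus_select_ligand_based <- function(scores, cutoff = -7.5,
                                          strict = FALSE) {
  consensus_select(scores, cutoff, min_targets = 2L,
                   protocol = "ligand_based", strict = strict)
}

#' Ligand efficiency
#'
#' Binding free energy per heavy (non-hydrogen) atom,
#' `LE = dG_b / heavy_atom_count` (kcal/mol per heavy atom) — a size-
#' normalized affinity used to compare ligands of different size.
#'
#' @param delta_g_b binding free energy, kcal/mol (vectorized).
#' @param heavy_atom_count number of non-hydrogen atoms (>= 1).
#' @return kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(delta_g_b, heavy_atom_count) {
  if (any(heavy_atom_count < 1)) {
    stop("heavy_atom_count must be at least 1")
  }
  delta_g_b / heavy_atom_count
}

#' Ligand-efficiency table from a binding free-energy table
#'
#' @param dg tibble with `compound_id`, `delta_g_b` (kcal/mol),
#'   `heavy_atom_count`.
#' @return the input with an `ligand_efficiency` column, sorted by it.
#' @export
ligand_efficiency_table <- function(dg) {
  dg |>
    dplyr::mutate(ligand_efficiency =
                    ligand_efficiency(.data$delta_g_b,
                                      .data$heavy_atom_count)) |>
    dplyr::arrange(.data$ligand_efficiency)
}

#' Read a docking score matrix from TSV
#'
#' Compounds x targets, first column `compound_id`, empty cells = no pose.
#' @param path TSV path.
#' @export
read_score_matrix <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = c("", "NA"))
}

#' Read a compound descriptor table from TSV
#' @param path TSV path.
#' @export
read_compound_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
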