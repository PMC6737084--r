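#' Resolve an atom selection against a topology
#'
#' The predicate is an unquoted expression over topology columns
#' (`atom_name`, `element`, `residue_index`, `residue_name`, `chain_id`,
#' `is_hydrogen`), e.g. `atom_name == "CA" & chain_id == "A"`. The result is a
#' sorted integer vector of atom ids — deterministic given the topology and
#' independent of row order. An empty selection is allowed (with a warning);
#' referencing an unknown field is an error.
#'
#' @param topology a `topology`.
#' @param predicate unquoted logical expression over topology columns; omit to
#'   select everything.
#' @param residue_range optional inclusive `c(start, end)` residue filter,
#'   applied after `predicate`.
#' @param chain optional chain id filter.
#' @return sorted integer atom ids (class `atom_selection`).
#' @export
resolve_selection <- function(topology, predicate = NULL,
                              residue_range = NULL, chain = NULL) {
  q <- rlang::enquo(predicate)
  keep <- rep(TRUE, nrow(topology))
  if (!rlang::quo_is_null(q)) {
    vars <- all.vars(rlang::quo_get_expr(q))
    env <- rlang::quo_get_env(q)
    unknown <- vars[!(vars %in% names(topology)) &
                      !vapply(vars, function(v)
                        !inherits(try(get(v, envir = env), silent = TRUE),
                                  "try-error"), logical(1))]
    if (length(unknown) > 0) {
      stop("selection predicate references unknown field(s): ",
           paste(unknown, collapse = ", "))
    }
    keep <- rlang::eval_tidy(q, data = as.data.frame(topology), env = env)
    keep[is.na(keep)] <- FALSE
  }
  if (!is.null(residue_range)) {
    keep <- keep & topology$residue_index >= residue_range[1] &
      topology$residue_index <= residue_range[2]
  }
  if (!is.null(chain)) keep <- keep & topology$chain_id %in% chain
  ids <- sort(topology$atom_id[keep])
  if (length(ids) == 0) warning("selection resolved to zero atoms")
  structure(as.integer(ids), class = "atom_selection")
}

# accept either a resolved selection or a raw id vector everywhere
as_selection_ids <- function(selection, topology) {
  ids <- sort(unique(as.integer(selection)))
  if (length(ids) > 0 && (min(ids) < 1 || max(ids) > nrow(topology))) {
    stop("selection contains atom ids outside the topology")
  }
  ids
}

#' Read a segment (helix) definition table
#'
#' Tab-separated columns `segment_name`, `chain_id`, `start`, `end` with
#' 1-based inclusive residue ranges, matching the way the ligand-binding
#' domain is partitioned into helices for correlation scoring.
#'
#' @param path TSV path.
#' @return a `segment_map` tibble.
#' @export
read_segments <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("segment_name", "chain_id", "start", "end")
  if (!all(need %in% names(tbl))) {
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  }
  make_segment_map(tbl$segment_name, tbl$start, tbl$end, tbl$chain_id)
}

#' Build a segment map in code
#'
#' @param segment_name character vector of segment labels (e.g. "H12").
#' @param start,end inclusive 1-based residue ranges.
#' @param chain_id chain each segment lives on.
#' @return a `segment_map` tibble. Ranges must be non-empty and a residue may
#'   belong to at most one segment per chain.
#' @export
make_segment_map <- function(segment_name, start, end, chain_id = "A") {
  tbl <- tibble::tibble(segment_name = as.character(segment_name),
                        chain_id = rep_len(chain_id, length(segment_name)),
                        start = as.integer(start), end = as.integer(end))
  if (any(tbl$end < tbl$start)) stop("segment ranges must be non-empty")
  if (anyDuplicated(tbl$segment_name)) stop("duplicate segment names")
  for (ch in unique(tbl$chain_id)) {
    sub <- tbl[tbl$chain_id == ch, ]
    res <- unlist(Map(seq, sub$start, sub$end))
    if (anyDuplicated(res)) {
      stop("segments overlap on chain ", ch,
           ": a residue may belong to at most one segment per chain")
    }
  }
  class(tbl) <- unique(c("segment_map", class(tbl)))
  tbl
}

# residue ids (chain + residue_index) of one segment
segment_residues <- function(segments, name) {
  row <- segments[segments$segment_name == name, ]
  if (nrow(row) != 1) stop("unknown segment: ", name)
  tibble::tibble(chain_id = row$chain_id,
                 residue_index = seq(row$start, row$end))
}
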