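#' Write / read a hill list in the PLUMED HILLS text dialect
#'
#' Columns: `time` (deposit step), one centre per CV, one sigma per CV,
#' `height`, `biasf` (1 for standard metadynamics). Interoperable with
#' standard plotting/summing tools.
#'
#' @param hills a `hill_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  ncv <- n_cv(hills)
  cvn <- paste0("cv", seq_len(ncv))
  hdr <- paste("#! FIELDS time", paste(cvn, collapse = " "),
               paste(paste0("sigma_", cvn), collapse = " "), "height biasf")
  m <- cbind(hills$step,
             as.matrix(hills[, paste0("center_", seq_len(ncv))]),
             as.matrix(hills[, paste0("sigma_", seq_len(ncv))]),
             hills$height, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#! FIELDS")]
  if (length(hdr) == 0) stop("not a HILLS file (no '#! FIELDS' header)")
  fields <- strsplit(sub("^#! FIELDS ", "", hdr[1]), "[[:space:]]+")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  colnames(m) <- fields
  ncv <- sum(grepl("^cv", fields) & !grepl("^sigma", fields))
  hill_set(m[, paste0("cv", seq_len(ncv)), drop = FALSE],
           widths = m[1, paste0("sigma_cv", seq_len(ncv))],
           height = m[, "height"], deposit_step = as.integer(m[, "time"]))
}

#' Write / read a free-energy surface as gridded TSV
#'
#' 1-CV surfaces have columns `cv1`, `free_energy`; 2-CV surfaces `cv1`,
#' `cv2`, `free_energy` (kJ/mol, minimum 0).
#'
#' @param fes a `free_energy_surface`.
#' @param path output path.
#' @export
write_fes <- function(fes, path) {
  tab <- fes_cell_index(fes)
  if (length(fes$axes) == 1) {
    out <- tibble::tibble(cv1 = tab$x, free_energy = tab$value)
  } else {
    out <- tibble::tibble(cv1 = tab$x, cv2 = tab$y, free_energy = tab$value)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  ax1 <- sort(unique(tab$cv1))
  if (!("cv2" %in% names(tab))) {
    values <- tab$free_energy[order(tab$cv1)]
    axes <- list(ax1)
    grid <- list(list(min = min(ax1), max = max(ax1), n = length(ax1)))
  } else {
    ax2 <- sort(unique(tab$cv2))
    values <- matrix(NA_real_, length(ax1), length(ax2))
    values[cbind(match(tab$cv1, ax1), match(tab$cv2, ax2))] <- tab$free_energy
    axes <- list(ax1, ax2)
    grid <- list(list(min = min(ax1), max = max(ax1), n = length(ax1)),
                 list(min = min(ax2), max = max(ax2), n = length(ax2)))
  }
  structure(list(values = values, axes = axes, grid = grid),
            class = "free_energy_surface")
}

#' Serialize / load a metadynamics configuration as YAML
#'
#' Round-trips the full configuration (hill height in kJ/mol, pace, wall
#' position, temperature, grids, seed) exactly, so a run can be reproduced
#' from its serialized config.
#'
#' @param config an [mtd_config()].
#' @param path YAML path.
#' @export
write_mtd_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_mtd_config
#' @export
read_mtd_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mtd_config(hill_height = raw$hill_height,
             hill_widths = as.numeric(raw$hill_widths),
             pace = raw$pace, temperature = raw$temperature,
             total_steps = raw$total_steps, dt = raw$dt,
             friction = raw$friction, mass = raw$mass,
             wall = raw$wall, grid = raw$grid,
             x0 = as.numeric(raw$x0), seed = raw$seed)
}

#' Write a cross-correlation or covariance matrix as TSV
#'
#' Long format: `atom_i`, `atom_j`, `value` for the upper triangle including
#' the diagonal.
#'
#' @param mat a `covariance_matrix` or `cross_correlation`.
#' @param path output path.
#' @export
write_correlation_matrix <- function(mat, path) {
  n <- length(mat$atom_ids)
  idx <- which(upper.tri(mat$values, diag = TRUE), arr.ind = TRUE)
  out <- tibble::tibble(atom_i = mat$atom_ids[idx[, 1]],
                        atom_j = mat$atom_ids[idx[, 2]],
                        value = mat$values[idx])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
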