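#' Read a protein topology from a PDB file
#'
#' Parses all ATOM/HETATM records (in file order) into a topology table. The
#' heavy lifting is done by [bio3d::read.pdb()]; a pre-validation pass checks
#' every coordinate record for the fixed-column fields so that malformed lines
#' are reported with their line number rather than silently mangled.
#'
#' Atom ids are renumbered contiguously from 1 (the original PDB serial is kept
#' in `pdb_serial`). The element is taken from columns 77-78 when present and
#' otherwise inferred from the atom name; `is_hydrogen` is `TRUE` exactly for
#' element H (or D).
#'
#' @param path path to a PDB file.
#' @param format currently only `"pdb"`.
#' @return a `topology`: a tibble with columns `atom_id`, `atom_name`,
#'   `element`, `residue_index`, `residue_name`, `chain_id`, `is_hydrogen`,
#'   `pdb_serial`.
#' @export
read_topology <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) stop("no ATOM/HETATM records in ", path)
  # columns 1-54 (record name .. z coordinate) are mandatory in the PDB format
  short <- which(is_coord & nchar(lines) < 54)
  if (length(short) > 0) {
    stop("malformed (truncated) coordinate record at line ", short[1],
         " of ", path)
  }
  bad_xyz <- which(is_coord &
                     is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))))
  if (length(bad_xyz) > 0) {
    stop("unparseable coordinates at line ", bad_xyz[1], " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- infer_element(at$elety[missing_el])
  }
  top <- tibble::tibble(
    atom_id = seq_len(nrow(at)),
    atom_name = trimws(at$elety),
    element = toupper(trimws(element)),
    residue_index = as.integer(at$resno),
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    is_hydrogen = toupper(trimws(element)) %in% c("H", "D"),
    pdb_serial = as.integer(at$eleno)
  )
  new_topology(top)
}

new_topology <- function(tbl) {
  stopifnot(all(c("atom_id", "atom_name", "element", "residue_index",
                  "residue_name", "chain_id", "is_hydrogen") %in% names(tbl)))
  if (anyDuplicated(tbl$atom_id) || !identical(as.integer(tbl$atom_id),
                                               seq_len(nrow(tbl)))) {
    stop("atom_id must be unique and contiguous from 1")
  }
  class(tbl) <- unique(c("topology", class(tbl)))
  tbl
}

# Element from a PDB atom name: strip digits/primes, take leading letters;
# names like "1HB1" are hydrogens, "CA" is carbon (calcium only as HETATM ion,
# which read.pdb reports with an explicit element symbol anyway).
infer_element <- function(atom_name) {
  nm <- gsub("[0-9\x27\"]", "", trimws(atom_name))
  el <- substr(nm, 1, 1)
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")]
  toupper(el)
}

#' Build a topology from scratch
#'
#' Convenience constructor used by the synthetic generators and in tests.
#'
#' @param atom_name,residue_index,residue_name,chain_id,element vectors
#'   recycled to a common length.
#' @return a `topology` tibble.
#' @export
make_topology <- function(atom_name, residue_index, residue_name = "ALA",
                          chain_id = "A", element = NULL) {
  n <- max(length(atom_name), length(residue_index))
  atom_name <- rep_len(atom_name, n)
  if (is.null(element)) element <- infer_element(atom_name)
  tbl <- tibble::tibble(
    atom_id = seq_len(n),
    atom_name = atom_name,
    element = rep_len(toupper(element), n),
    residue_index = as.integer(rep_len(residue_index, n)),
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    is_hydrogen = rep_len(toupper(element), n) %in% c("H", "D")
  )
  new_topology(tbl)
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x), " atoms, ",
      length(unique(paste(x$chain_id, x$residue_index))), " residues, ",
      length(unique(x$chain_id)), " chain(s)\n", sep = "")
  NextMethod()
}
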