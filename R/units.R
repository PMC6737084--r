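#' Energy unit conversion
#'
#' All trajectory coordinates in this package are in Angstrom and all
#' metadynamics hill heights / bias energies in kJ/mol, while dissociation
#' barriers and docking scores are conventionally quoted in kcal/mol. This is
#' the single place where the 1 kcal = 4.184 kJ conversion lives.
#'
#' @param x numeric energy value(s).
#' @param from,to one of `"kJ/mol"`, `"kcal/mol"`.
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_energy(4.184, "kJ/mol", "kcal/mol") # 1
#' @export
convert_energy <- function(x, from = c("kJ/mol", "kcal/mol"),
                           to = c("kcal/mol", "kJ/mol")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "kJ/mol") x / 4.184 else x * 4.184
}

#' Boltzmann constant in kJ/(mol K)
#' @export
KB_KJ_MOL_K <- 0.0083144621
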