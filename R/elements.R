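# Element property tables. Van der Waals radii are the Bondi set; covalent
# radii are the Cordero single-bond values; masses are standard atomic
# weights. All radii in Angstrom, masses in u.

.element_table <- function() {
  tibble::tribble(
    ~element, ~vdw_A, ~covalent_A, ~mass,
    "H",  1.20, 0.31,  1.008,
    "C",  1.70, 0.76, 12.011,
    "N",  1.55, 0.71, 14.007,
    "O",  1.52, 0.66, 15.999,
    "F",  1.47, 0.57, 18.998,
    "P",  1.80, 1.07, 30.974,
    "S",  1.80, 1.05, 32.06,
    "Cl", 1.75, 1.02, 35.45,
    "Br", 1.85, 1.20, 79.904,
    "I",  1.98, 1.39, 126.904
  )
}

#' Look up element properties
#'
#' Returns van der Waals radius (Bondi), covalent radius (Cordero) and
#' standard atomic weight for element symbols. Unknown symbols are an error:
#' every downstream descriptor needs a defined radius.
#'
#' @param element Character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @param radii Optional tibble overriding the built-in table; must have
#'   columns `element`, `vdw_A`, `covalent_A`, `mass`.
#' @return A tibble with one row per input symbol, columns `element`,
#'   `vdw_A`, `covalent_A`, `mass`.
#' @export
#' @examples
#' element_properties(c("C", "O", "H"))
element_properties <- function(element, radii = NULL) {
  tab <- radii %||% .element_table()
  idx <- match(element, tab$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "chameleonics_unknown_element")
  }
  tab[idx, ]
}
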