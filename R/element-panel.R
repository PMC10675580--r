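#' The 64-element analytical panel
#'
#' Elemental fingerprinting of egg components is based on a fixed panel of 64
#' elements measured by ICP-MS, organised into chemically meaningful groups:
#' the five macro-minerals, heavy/trace metals (including all twelve metals
#' with tabulated oral reference doses), alkaline and alkaline-earth metals,
#' the rare earth elements (REE), technology-critical elements (TCE),
#' platinum-group elements (PGE), transition and post-transition metals, and
#' one actinide.
#'
#' @return A named list of character vectors; names are group labels, values
#'   are IUPAC element symbols. The groups are disjoint and together contain
#'   64 unique symbols.
#' @examples
#' panel <- elementPanel()
#' lengths(panel)
#' sum(lengths(panel))  # 64
#' @export
elementPanel <- function() {
    list(
        macro      = c("Na", "Mg", "P", "K", "Ca"),
        heavy      = c("Al", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
                       "As", "Se", "Ag", "Cd", "Sn", "Hg", "Pb"),
        alkaline   = c("Li", "Cs", "Rb", "Be", "Ba", "Sr"),
        ree        = c("Sc", "Y", "La", "Ce", "Pr", "Nd", "Sm", "Eu",
                       "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu"),
        tce        = c("Te", "Ge", "Ga", "In", "Nb", "Ta"),
        pge        = c("Pt", "Pd", "Rh", "Os", "Ir", "Ru"),
        transition = c("Zr", "Hf", "W", "Re", "Ti", "V", "Mo", "Bi", "Tl"),
        actinide   = "Th"
    )
}

#' All element symbols of the panel
#'
#' @return Character vector of the 64 element symbols, in panel group order.
#' @export
panelElements <- function() unname(unlist(elementPanel()))

#' Group label for each panel element
#'
#' @param elements character vector of element symbols.
#' @return Character vector of group labels (NA for symbols outside the
#'   panel).
#' @export
elementGroup <- function(elements) {
    panel <- elementPanel()
    map <- rep(names(panel), lengths(panel))
    names(map) <- unlist(panel)
    unname(map[elements])
}

#' Write / read the panel definition as JSON
#'
#' Serialises the group structure so external tools can consume the panel
#' definition.
#'
#' @param path file path of the JSON document.
#' @return `writeElementPanel` returns `path` invisibly; `readElementPanel`
#'   returns a named list like [elementPanel()].
#' @export
writeElementPanel <- function(path) {
    jsonlite::write_json(elementPanel(), path, pretty = TRUE)
    invisible(path)
}

#' @rdname writeElementPanel
#' @export
readElementPanel <- function(path) {
    panel <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(panel, as.character)
}
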