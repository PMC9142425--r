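# Environment caching the isotope-mass table after first load.
.fluoroscreen_env <- new.env(parent = emptyenv())

#' Monoisotopic isotope-mass table
#'
#' Returns the bundled table of monoisotopic masses (mass of the most
#' abundant isotope, in Da) used by all exact-mass arithmetic in the
#' package, together with the electron rest mass. The table ships as a
#' versioned plain-text resource under `extdata/` so that independent
#' checks can load it without going through package code.
#'
#' @return A named numeric vector of masses in Da, one element per symbol.
#'   The electron mass is stored under the name `"e-"`.
#' @export
#' @examples
#' isotope_masses()[["F"]]
isotope_masses <- function() {
  if (is.null(.fluoroscreen_env$isotopes)) {
    path <- system.file("extdata", "isotope_masses.tsv",
                        package = "fluoroscreen", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    masses <- stats::setNames(as.numeric(tab$mass), tab$element)
    if (any(masses <= 0)) stop("isotope-mass table contains non-positive mass")
    .fluoroscreen_env$isotopes <- masses
  }
  .fluoroscreen_env$isotopes
}

electron_mass <- function() isotope_masses()[["e-"]]

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula (`"C8H5F11O2"`) into a named
#' integer vector of element counts. Charges are never encoded in the
#' formula; ion species are handled separately by [anion_mz()].
#'
#' @param text A single formula string. Element symbols are one capital
#'   letter optionally followed by one lowercase letter; counts are optional
#'   multi-digit integers (absent count means 1).
#' @return Named integer vector of element counts (a formula composition).
#' @export
#' @examples
#' parse_formula("C8H5F11O2")
#' parse_formula("CF3")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula: '", text, "'")
  symbols <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- setdiff(names(isotope_masses()), "e-")
  bad <- setdiff(symbols, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  comp <- tapply(counts, symbols, sum)
  out <- as.integer(comp)
  names(out) <- names(comp)
  hill_order(out)
}

# Order a composition in Hill convention: C, H, then alphabetical.
hill_order <- function(comp) {
  els <- names(comp)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  comp[ord]
}

#' Canonical Hill string of a composition
#'
#' @param comp Named integer vector as returned by [parse_formula()].
#' @return A single Hill-notation formula string.
#' @export
formula_string <- function(comp) {
  comp <- hill_order(comp[comp > 0])
  if (!length(comp)) return("")
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the monoisotopic mass from the bundled
#' isotope table. An empty composition has mass 0.
#'
#' @param comp Named integer vector of element counts, or a formula string
#'   (parsed with [parse_formula()]).
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (!length(comp)) return(0)
  masses <- isotope_masses()
  miss <- setdiff(names(comp), names(masses))
  if (length(miss))
    stop("element(s) missing from isotope table: ", paste(miss, collapse = ", "))
  sum(masses[names(comp)] * comp)
}

#' Theoretical m/z of a singly charged anion
#'
#' Computes the m/z of either the deprotonated molecule `[M-H]-` (neutral
#' mass minus one hydrogen plus one electron) or an intact anion whose
#' formula already describes the charged fragment (formula mass plus one
#' electron). The electron mass is included: at the mass accuracy of
#' Orbitrap data its neglect shifts small fragments such as C2F5- by
#' several ppm, enough to break a 10 ppm annotation window.
#'
#' @param comp Composition or formula string of the neutral molecule
#'   (for `"[M-H]-"`) or of the charged fragment (for `"anion"`).
#' @param ion Ion species: `"[M-H]-"` (default) or `"anion"`.
#' @return m/z of the singly charged anion.
#' @export
#' @examples
#' anion_mz("C8H5F11O2")        # deprotonated 5:3 FTCA
#' anion_mz("CF3", "anion")     # trifluoromethyl fragment
anion_mz <- function(comp, ion = c("[M-H]-", "anion")) {
  ion <- match.arg(ion)
  if (is.character(comp)) comp <- parse_formula(comp)
  m <- monoisotopic_mass(comp)
  if (ion == "[M-H]-") {
    if (is.na(comp["H"]) || comp["H"] < 1L)
      stop("cannot deprotonate a composition with no hydrogen")
    m - isotope_masses()[["H"]] + electron_mass()
  } else {
    m + electron_mass()
  }
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Mass defect of an m/z value
#'
#' Difference between an m/z value and its nearest integer,
#' `mz - round(mz)`, lying in (-0.5, 0.5]. Heavily fluorinated molecules
#' have near-zero to negative mass defects, which is what makes the defect
#' a useful PFAS filter.
#'
#' @param mz m/z value(s), > 0.
#' @return Mass defect(s) in amu.
#' @export
#' @examples
#' mass_defect(370.0546)
mass_defect <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive")
  mz - round(mz)
}

#' Kendrick mass transformation
#'
#' Rescales m/z so that a chosen repeat unit (CF2 by default) has integer
#' mass: `KM = mz * nominal(base) / exact(base)`. Members of a homologous
#' series differing by whole repeat units then share one Kendrick mass
#' defect `KM - round(KM)`.
#'
#' @param mz m/z value(s), > 0.
#' @param base Composition or formula string of the repeat unit
#'   (default `"CF2"`). Its nominal mass is the integer sum of nominal
#'   atomic masses (CF2 -> 50).
#' @return A list with elements `kendrick_mass`, `kmd`, `base`,
#'   `base_exact`, `base_nominal`.
#' @export
#' @examples
#' kendrick_transform(412.9664)$kmd
kendrick_transform <- function(mz, base = "CF2") {
  if (any(mz <= 0)) stop("m/z must be positive")
  if (is.character(base)) base <- parse_formula(base)
  exact <- monoisotopic_mass(base)
  if (exact <= 0) stop("base unit must have positive mass")
  nominal <- nominal_mass(base)
  km <- mz * nominal / exact
  list(kendrick_mass = km, kmd = km - round(km),
       base = formula_string(base), base_exact = exact,
       base_nominal = nominal)
}

# Integer nominal mass of a composition (sum of rounded isotope masses).
nominal_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  masses <- isotope_masses()
  as.integer(sum(round(masses[names(comp)]) * comp))
}
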