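# Molecular-formula arithmetic and the offline compound/adduct registry.
#
# All masses are monoisotopic and in unified atomic mass units (u); m/z is in
# thomson (Th). Adduct shifts are electron-corrected so that e.g. the bare
# proton adduct of a massless neutral gives m/z 1.007276.

#' Monoisotopic atomic masses
#'
#' IUPAC monoisotopic atomic masses (mass of the most abundant isotope) for
#' the elements handled by [parse_formula()]. Carbon is exactly 12 by
#' definition of the unified atomic mass unit.
#'
#' @return Named numeric vector, element symbol -> mass in u.
#' @export
#' @examples
#' element_masses()[["C"]]  # 12 exactly
element_masses <- function() {
  c(
    H  = 1.0078250319,
    C  = 12.0,
    N  = 14.0030740052,
    O  = 15.9949146221,
    Na = 22.9897692820,
    K  = 38.9637064864,
    S  = 31.9720711744,
    P  = 30.9737619984,
    F  = 18.9984031627,
    Cl = 34.9688526820,
    Se = 79.9165218000,
    I  = 126.9044719000
  )
}

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as `"C5H4N4O"` into a named count vector. An omitted
#' count means 1. Repeated element symbols are summed.
#'
#' @param text Single non-empty formula string.
#' @return Named integer vector of element counts, in Hill order
#'   (C, H, then other elements alphabetically).
#' @export
#' @examples
#' parse_formula("C5H4N4O")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula: '", text, "'")
  sym <- sub("[0-9]+$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(n) || any(n < 1L))
    stop("malformed element count in formula: '", text, "'")
  bad <- setdiff(unique(sym), names(element_masses()))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(n, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[hill_order(names(out))]
}

# Hill order: C first, H second, remaining symbols alphabetical.
hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  intersect(c("C", "H", rest), symbols)
}

#' Serialize a molecular formula to Hill notation
#'
#' Inverse of [parse_formula()]; `parse_formula(format_formula(f))` equals `f`.
#'
#' @param formula Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(formula) {
  formula <- formula[hill_order(names(formula))]
  paste0(names(formula), ifelse(formula == 1L, "", formula), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Named count vector as returned by [parse_formula()], or a
#'   formula string.
#' @param masses Element mass table; defaults to [element_masses()].
#' @return Neutral monoisotopic mass in u.
#' @export
#' @examples
#' monoisotopic_mass("C5H4N4O")  # hypoxanthine, 136.0385
monoisotopic_mass <- function(formula, masses = element_masses()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L || any(formula < 0))
    stop("formula must have at least one element with a positive count")
  missing <- setdiff(names(formula), names(masses))
  if (length(missing))
    stop("element(s) missing from mass table: ", paste(missing, collapse = ", "))
  sum(masses[names(formula)] * formula)
}

#' Built-in positive-mode adduct definitions
#'
#' Electron-corrected mass shifts for the common positive-mode ESI adducts
#' (protonation, sodiation, potassiation, ammonium, water/ammonia neutral
#' loss, and the two doubly charged forms). m/z of an adduct is
#' `(M + mass_shift) / charge`.
#'
#' @return Data frame with columns `name`, `mass_shift` (u), `charge`.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("M+H[1+]", "M+Na[1+]", "M+NH3[1+]", "M+K[1+]",
             "M-H2O[1+]", "M-NH3[1+]", "M+2H[2+]", "M+H+Na[2+]"),
    mass_shift = c(1.007276, 22.989218, 18.033823, 38.963158,
                   -17.003289, -16.019274, 2.014552, 23.996494),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

# In-source tie-break priority for annotation: typical positive-mode ESI
# abundance order; doubly charged species last.
adduct_priority <- function(names) {
  order_ref <- c("M+H[1+]", "M+Na[1+]", "M+NH3[1+]", "M+K[1+]",
                 "M-H2O[1+]", "M-NH3[1+]", "M+2H[2+]", "M+H+Na[2+]")
  p <- match(names, order_ref)
  p[is.na(p)] <- length(order_ref) + 1L
  p
}

resolve_adduct <- function(adduct, adducts = default_adducts()) {
  if (is.character(adduct)) {
    i <- match(adduct, adducts$name)
    if (is.na(i)) stop("unknown adduct: ", adduct)
    adduct <- adducts[i, ]
  }
  if (is.null(adduct$mass_shift) || is.null(adduct$charge))
    stop("adduct must have mass_shift and charge")
  if (adduct$charge < 1) stop("adduct charge must be >= 1")
  adduct
}

#' m/z of an adduct of a neutral molecule
#'
#' @param neutral_mass Neutral monoisotopic mass in u (>= 0).
#' @param adduct Adduct name (looked up in `adducts`) or a list/one-row data
#'   frame with `mass_shift` and `charge`.
#' @param adducts Adduct table used for name lookup.
#' @return m/z in Th.
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C8H11NO3"), "M+H[1+]")  # pyridoxine, 170.0812
adduct_mz <- function(neutral_mass, adduct, adducts = default_adducts()) {
  if (any(neutral_mass < 0)) stop("neutral_mass must be >= 0")
  a <- resolve_adduct(adduct, adducts)
  mz <- (neutral_mass + a$mass_shift) / a$charge
  if (any(mz <= 0)) stop("nonphysical m/z <= 0 for adduct ", a$name)
  mz
}

#' Neutral mass recovered from an adduct m/z
#'
#' Exact inverse of [adduct_mz()].
#'
#' @inheritParams adduct_mz
#' @param mz Observed m/z in Th.
#' @return Neutral mass in u.
#' @export
neutral_mass_from_mz <- function(mz, adduct, adducts = default_adducts()) {
  a <- resolve_adduct(adduct, adducts)
  mz * a$charge - a$mass_shift
}

#' Signed ppm error of an observed m/z against a theoretical m/z
#'
#' @param observed,theoretical m/z values in Th.
#' @return (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Load a compound registry and adduct table from delimited files
#'
#' The registry is the offline stand-in for interactive spectral-database
#' lookups: tab-separated with columns `name`, `formula`, `cas`, `kegg`,
#' `ec_links` (semicolon-joined EC codes), `pathways` (semicolon-joined) and
#' `verified` (logical; whether the catalogued observation is mass-consistent
#' with its stated adduct). Neutral monoisotopic masses are computed from the
#' formulas at load time.
#'
#' @param compound_file Path to the compound table. Defaults to the packaged
#'   registry of named reference metabolites.
#' @param adduct_file Path to the adduct table (columns `name`, `mass_shift`,
#'   `charge`). Defaults to the packaged positive-mode adduct set.
#' @return List with class `"compound_registry"`: `compounds` (data frame with
#'   added `neutral_mass`) and `adducts`.
#' @export
load_registry <- function(
    compound_file = system.file("extdata", "compounds.tsv", package = "duomics"),
    adduct_file = system.file("extdata", "adducts.tsv", package = "duomics")) {
  comp <- utils::read.delim(compound_file, stringsAsFactors = FALSE,
                            colClasses = "character", comment.char = "#")
  need <- c("name", "formula", "cas", "kegg", "ec_links", "pathways", "verified")
  miss <- setdiff(need, names(comp))
  if (length(miss))
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  dup <- comp$name[duplicated(comp$name)]
  if (length(dup))
    stop("duplicate compound name(s): ", paste(unique(dup), collapse = ", "))
  comp$neutral_mass <- vapply(seq_len(nrow(comp)), function(i) {
    tryCatch(monoisotopic_mass(comp$formula[i]),
             error = function(e) stop("compound table line ", i + 1L, " ('",
                                      comp$name[i], "'): ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  has_cas <- !is.na(comp$cas) & nzchar(comp$cas)
  bad_cas <- has_cas & !grepl("^[0-9]+-[0-9]+-[0-9]$", comp$cas)
  if (any(bad_cas))
    stop("malformed CAS number(s) at compound table line(s) ",
         paste(which(bad_cas) + 1L, collapse = ", "))
  comp$verified <- toupper(comp$verified) %in% c("TRUE", "T", "1", "YES")

  add <- utils::read.delim(adduct_file, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("name", "mass_shift", "charge") %in% names(add)))
    stop("adduct table needs columns name, mass_shift, charge")
  add$mass_shift <- as.numeric(add$mass_shift)
  add$charge <- as.integer(add$charge)
  if (anyNA(add$mass_shift) || anyNA(add$charge))
    stop("adduct table has non-numeric mass_shift/charge")
  if (any(add$charge < 1L)) stop("adduct charge must be >= 1")
  if (anyDuplicated(add$name)) stop("duplicate adduct name(s) in adduct table")

  structure(list(compounds = comp, adducts = add), class = "compound_registry")
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("compound registry:", nrow(x$compounds), "compounds,",
      nrow(x$adducts), "adducts\n")
  invisible(x)
}

# Split a semicolon-joined field into a character vector (empty -> character(0)).
split_links <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' EC codes linked to each registry compound
#'
#' @param registry A `compound_registry`.
#' @return Named list, compound name -> character vector of EC codes.
#' @export
registry_ec_links <- function(registry) {
  out <- lapply(registry$compounds$ec_links, split_links)
  names(out) <- registry$compounds$name
  out
}
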