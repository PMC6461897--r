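#' Standard atomic weights
#'
#' Look up standard atomic weights (Da) by element symbol. Covers the
#' elements that occur in small-molecule ligands and protein structures;
#' an unknown symbol falls back to the mass of carbon with a warning, so a
#' nonstandard PDBQT atom type can never abort a run.
#'
#' @param element Character vector of element symbols (case-insensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of masses in Da, same length as `element`.
#' @examples
#' atomic_mass(c("C", "O", "Zn"))
#' @export
atomic_mass <- function(element) {
  stopifnot(is.character(element))
  key <- standardize_element(element)
  m <- unname(.atomic_weights[key])
  unknown <- is.na(m)
  if (any(unknown)) {
    warning(
      "unknown element symbol(s) ",
      paste(unique(element[unknown]), collapse = ", "),
      "; using carbon mass ", .atomic_weights[["C"]], " Da as fallback",
      call. = FALSE
    )
    m[unknown] <- .atomic_weights[["C"]]
  }
  m
}

# CIAAW 2021 conventional values, enough coverage for ligands and proteins
.atomic_weights <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  Li = 6.94, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

# "CL"/"cl" -> "Cl", "c" -> "C"
standardize_element <- function(element) {
  el <- trimws(element)
  paste0(
    toupper(substr(el, 1L, 1L)),
    tolower(substr(el, 2L, nchar(el)))
  )
}

# Map AutoDock atom types (PDBQT cols 78-79) to element symbols.
# Aromatic carbon is "A"; polar H is "HD"; acceptors carry a trailing "A".
element_from_pdbqt_type <- function(type) {
  t <- toupper(trimws(type))
  mapped <- c(
    A = "C", C = "C", N = "N", NA. = "N", NS = "N",
    OA = "O", OS = "O", O = "O", SA = "S", S = "S",
    HD = "H", HS = "H", H = "H", P = "P", F = "F",
    CL = "Cl", BR = "Br", I = "I", MG = "Mg", MN = "Mn",
    ZN = "Zn", CA = "Ca", FE = "Fe"
  )
  names(mapped)[names(mapped) == "NA."] <- "NA"
  out <- unname(mapped[t])
  # fall back to the leading letters of the type, then let atomic_mass()
  # handle anything still unknown
  miss <- is.na(out)
  out[miss] <- standardize_element(sub("[^A-Za-z].*$", "", t[miss]))
  out[out == ""] <- "C"
  out
}
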