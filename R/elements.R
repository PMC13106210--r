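# Element property tables: Bondi van der Waals radii (Angstrom) and atomic
# masses (amu). Unknown elements fall back to 1.70 A / 12.011 amu with a
# warning (carbon-like), per the package's documented convention.

.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
              "FE", "ZN", "MG", "NA", "K", "CA", "MN", "CU", "SE"),
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
              2.00, 1.39, 1.73, 2.27, 2.75, 2.31, 2.00, 1.40, 1.90),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45,
              79.904, 126.904, 55.845, 65.38, 24.305, 22.990, 39.098,
              40.078, 54.938, 63.546, 78.971),
  stringsAsFactors = FALSE
)

.default_vdw <- 1.70
.default_mass <- 12.011

# Two-letter element symbols recognised when inferring from atom names of
# hetero records (metal ions, halogens); protein atom names like "CA"/"CD"
# always mean carbon.
.two_letter_elements <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU", "SE")

#' @noRd
element_properties <- function(element) {
  idx <- match(toupper(element), .element_table$element)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using default vdW radius ", .default_vdw, " A", call. = FALSE)
  }
  data.frame(
    vdw  = ifelse(unknown, .default_vdw, .element_table$vdw[idx]),
    mass = ifelse(unknown, .default_mass, .element_table$mass[idx])
  )
}

# Infer an element symbol from a PDB atom name. `het` marks HETATM records,
# where two-letter symbols (CL, FE, ...) are plausible; for ATOM records the
# first alphabetic character wins so "CA" is carbon, not calcium.
#' @noRd
infer_element <- function(name, het = FALSE) {
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(name)))
  if (nchar(nm) == 0L) stop("cannot infer element from atom name '", name, "'")
  if (het && nm %in% .two_letter_elements) return(nm)
  # names such as 1HB / HG11 are hydrogens once digits are stripped
  substr(nm, 1L, 1L)
}
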