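#' Element property table
#'
#' Standard atomic masses (Da), Bondi van der Waals radii (Angstrom) and
#' electron counts (used as q-independent X-ray form factors) for the elements
#' commonly found in protein structures. Elements missing from the table fall
#' back to carbon-like values with a warning.
#'
#' @format A data.frame with columns `element`, `mass`, `radius`, `electrons`.
#' @export
element_table <- function() {
  data.frame(
    element   = c("H",  "C",  "N",  "O",  "S",  "P",  "SE", "ZN", "FE",
                  "MG", "CA", "NA", "K",  "CL", "MN", "CU", "I",  "BR", "F"),
    mass      = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971,
                  65.38, 55.845, 24.305, 40.078, 22.990, 39.098, 35.45,
                  54.938, 63.546, 126.904, 79.904, 18.998),
    # Bondi (1964) vdW radii; metals set to commonly used working values.
    radius    = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.90, 1.39, 1.40,
                  1.73, 1.80, 2.27, 2.75, 1.75, 1.40, 1.40, 1.98, 1.85, 1.47),
    electrons = c(1, 6, 7, 8, 16, 15, 34, 30, 26, 12, 20, 11, 19, 17,
                  25, 29, 53, 35, 9),
    stringsAsFactors = FALSE
  )
}

#' Look up element properties
#'
#' @param element element symbol(s).
#' @param what `"mass"` (Da), `"radius"` (Bondi vdW, Angstrom) or
#'   `"electrons"` (electron count, the constant X-ray form factor).
#' @return numeric vector, one value per element.
#' @export
element_property <- function(element, what = c("mass", "radius", "electrons")) {
  what <- match.arg(what)
  tab <- element_table()
  idx <- match(toupper(element), tab$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using carbon-like defaults")
    idx[is.na(idx)] <- match("C", tab$element)
  }
  tab[[what]][idx]
}

#' Infer the element symbol from a PDB atom name
#'
#' Used when PDB columns 77-78 are blank. Two-letter elements found in
#' proteins (Zn, Fe, Se, ...) are recognised when the full atom name matches;
#' otherwise the first alphabetic character wins (so `1HG1` is hydrogen and
#' `CA` inside an amino-acid residue is carbon).
#'
#' @param name atom-name string(s)
#' @param resname residue name(s), used to disambiguate calcium ions (`CA` in
#'   residue `CA`) from alpha carbons.
#' @return element symbol(s)
#' @export
guess_element <- function(name, resname = "") {
  nm <- toupper(trimws(name))
  rn <- toupper(trimws(resname))
  two <- c("ZN", "FE", "MG", "NA", "CL", "MN", "CU", "SE", "BR")
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    stripped <- gsub("[^A-Z]", "", nm[i])
    if (nm[i] %in% two && (rn[min(i, length(rn))] %in% c(two, "CA", "K", "I"))) {
      out[i] <- nm[i]
    } else if (grepl("^[0-9]*H", nm[i])) {
      out[i] <- "H"
    } else {
      out[i] <- substr(stripped, 1, 1)
    }
  }
  out
}

# Hydrogen-bond donor / acceptor heavy atoms per standard residue.  The table
# is deliberately small and swappable: detect_hbonds() takes it as an
# argument.  Backbone N (donor, except proline) and backbone O (acceptor) are
# implicit for every amino acid.
.hbond_table <- function() {
  list(
    donors = list(
      ARG = c("NE", "NH1", "NH2"), LYS = "NZ", SER = "OG", THR = "OG1",
      TYR = "OH", ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
      TRP = "NE1", CYS = "SG"
    ),
    acceptors = list(
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
      GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
      HIS = c("ND1", "NE2"), MET = "SD"
    )
  )
}

# Charged side-chain atoms for salt-bridge detection.
.saltbridge_atoms <- function() {
  list(
    acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    basic  = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))
  )
}
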