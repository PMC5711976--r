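#' @name residue-alphabet
#' @title The 23-category residue alphabet
#'
#' @description
#' Twenty standard amino acids plus three chemically distinct variants that
#' carry their own shift statistics: oxidised cysteine (disulfide), cis
#' proline, and protonated histidine.  Internally a residue state is a
#' single string code: the one-letter code for standard residues, or
#' `"C_ox"`, `"P_cis"`, `"H_plus"` for the variants.
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

VARIANT_CODES <- c(cys_oxidized = "C_ox", pro_cis = "P_cis",
                   his_protonated = "H_plus")
VARIANT_PARENT <- c(C_ox = "C", P_cis = "P", H_plus = "H")
ALPHABET23 <- c(AA20, unname(VARIANT_CODES))

#' Build a residue-state code
#'
#' @param aa one-letter amino-acid code (one of the 20 standard letters).
#' @param variant `"none"` (default), `"cys_oxidized"` (C only),
#'   `"pro_cis"` (P only) or `"his_protonated"` (H only).
#' @return a single string in the 23-letter alphabet.
#' @export
#' @examples
#' residue_state("A")            # "A"
#' residue_state("C", "cys_oxidized")  # "C_ox"
residue_state <- function(aa, variant = "none") {
  if (!aa %in% AA20)
    stop("unknown amino-acid letter: ", aa, call. = FALSE)
  if (identical(variant, "none") || is.na(variant) || variant == "")
    return(aa)
  code <- VARIANT_CODES[variant]
  if (is.na(code))
    stop("unknown variant: ", variant, call. = FALSE)
  if (VARIANT_PARENT[[code]] != aa)
    stop("variant '", variant, "' not permitted for residue ", aa,
         call. = FALSE)
  unname(code)
}

#' Parent amino acid of a residue-state code
#' @param code residue-state code(s) in the 23-letter alphabet.
#' @return one-letter code(s).
#' @export
residue_parent <- function(code) {
  p <- VARIANT_PARENT[code]
  unname(ifelse(is.na(p), code, p))
}

# Nucleus from the atom name's first letter: C -> 13C, H -> 1H, N -> 15N.
atom_nucleus <- function(atom) {
  first <- substr(atom, 1L, 1L)
  out <- c(C = "13C", H = "1H", N = "15N")[first]
  if (anyNA(out))
    stop("cannot infer nucleus for atom(s): ",
         paste(unique(atom[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

# Default kernel-bandwidth floor per atom (ppm): 1H is sharper than 13C/15N.
bw_floor_for <- function(atom) {
  ifelse(atom_nucleus(atom) == "1H", 0.02, 0.05)
}

# pH bin assignment: the model is parameterised at exactly two pH values.
assign_ph_bin <- function(ph) ifelse(ph <= 4.5, 2.8, 6.4)

# Atoms that do not exist chemically for a residue type (skipped silently).
atom_exists <- function(res, atom) {
  parent <- residue_parent(res)
  !((parent == "G" & atom %in% c("CB", "HB")) |
      (parent == "P" & atom %in% c("H", "HN")))
}
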