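# Molecular-formula arithmetic for tetraether lipid identification.
#
# GDGT homologue series are related by small, fixed composition changes:
# one extra methyl group (+CH2, +14 Da nominal), one extra ring (-H2, -2 Da),
# or the GMGT carbon bridge covalently linking the two alkyl chains (-H2).
# Identification by accurate mass only needs monoisotopic sums and singly
# charged adduct masses, both handled here.

# IUPAC monoisotopic atomic masses (Da)
.tl_atomic_masses <- c(
  C  = 12.000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  Na = 22.9897693
)

# singly charged adduct masses (Da added to the neutral monoisotopic mass);
# the proton constant 1.00728 absorbs the electron-mass deficit
.tl_adduct_masses <- c(
  "M+H"   = 1.00728,
  "M+NH4" = 18.03383,
  "M+Na"  = 22.98922
)

#' Parse a molecular formula string
#'
#' Turns a Hill-style formula such as `"C66H132O6"` into a named integer
#' vector of element counts. Supported elements are C, H, N, O and Na.
#'
#' @param formula A formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C66H132O6")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
      tl_abort("formula must be a single non-empty string or named count vector")
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (paste(tokens, collapse = "") != formula) {
      tl_abort(sprintf("cannot parse formula '%s'", formula))
    }
    elems <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Za-z]+", "", tokens)
    counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
    names(counts) <- elems
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.tl_atomic_masses))
  if (length(unknown) > 0) {
    tl_abort(sprintf("unknown element(s) in formula: %s",
                     paste(unknown, collapse = ", ")))
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    tl_abort("element counts must be non-negative integers")
  }
  if (sum(counts) < 1) {
    tl_abort("formula must contain at least one atom")
  }
  counts[counts > 0]
}

#' Write element counts back as a formula string
#'
#' @param counts Named numeric vector of element counts.
#' @return A formula string in C, H, N, O, Na order.
#' @export
format_formula <- function(counts) {
  counts <- parse_formula(counts)
  ord <- intersect(names(.tl_atomic_masses), names(counts))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of IUPAC monoisotopic atomic masses (C 12.000000, H 1.0078250,
#' N 14.0030740, O 15.9949146, Na 22.9897693).
#'
#' @inheritParams parse_formula
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C66H132O6")  # 1021.00239
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .tl_atomic_masses[names(counts)])
}

#' Adduct m/z of a neutral species
#'
#' Computes the mass-to-charge ratio of a singly charged adduct ion
#' (`M+H`, `M+NH4` or `M+Na`) of the neutral molecule.
#'
#' @inheritParams parse_formula
#' @param adduct Adduct label, one of `"M+H"`, `"M+NH4"`, `"M+Na"`.
#' @return The adduct m/z in Da (charge +1).
#' @examples
#' adduct_mz("C66H132O6", "M+H")   # 1022.0097
#' round_mz(adduct_mz("C66H132O6", "M+H"))  # 1022
#' @seealso [round_mz()]
#' @export
adduct_mz <- function(formula, adduct) {
  if (!is.character(adduct) || length(adduct) != 1L ||
      !adduct %in% names(.tl_adduct_masses)) {
    tl_abort(sprintf("unsupported adduct '%s'; expected one of %s",
                     paste(adduct, collapse = ","),
                     paste(names(.tl_adduct_masses), collapse = ", ")))
  }
  monoisotopic_mass(formula) + .tl_adduct_masses[[adduct]]
}

#' Round an m/z to its nominal integer mass
#'
#' Rounds half away from zero, so 1021.5 becomes 1022.
#'
#' @param mz Numeric m/z value(s).
#' @return Integer nominal mass(es).
#' @export
round_mz <- function(mz) {
  as.integer(round_half_away(mz))
}

#' Apply a homologue-series step to a formula
#'
#' Homologue series of branched and overly branched GDGTs are generated from
#' a base species by repeated small composition changes: `"methylation"`
#' adds CH2 (+14.01565 Da), `"ring"` removes H2 (one additional cyclopentane
#' ring, -2.01565 Da), and `"gmgt_bridge"` also removes H2 (the covalent
#' C-C bridge between the two alkyl chains that turns a GDGT into a GMGT).
#' Steps commute because each is an additive composition delta.
#'
#' @inheritParams parse_formula
#' @param step Character vector of steps, each one of `"methylation"`,
#'   `"ring"`, `"gmgt_bridge"`; applied in order.
#' @return Named count vector of the resulting formula.
#' @examples
#' format_formula(apply_series_step("C66H132O6", "methylation"))  # C67H134O6
#' format_formula(apply_series_step("C66H132O6", "gmgt_bridge"))  # C66H130O6
#' @export
apply_series_step <- function(formula, step) {
  counts <- parse_formula(formula)
  full <- setNames(numeric(length(.tl_atomic_masses)), names(.tl_atomic_masses))
  full[names(counts)] <- counts
  for (s in step) {
    delta <- switch(s,
      methylation = c(C = 1, H = 2),
      ring        = c(H = -2),
      gmgt_bridge = c(H = -2),
      tl_abort(sprintf("unknown series step '%s'", s))
    )
    full[names(delta)] <- full[names(delta)] + delta
    if (any(full < 0)) {
      tl_abort(sprintf("series step '%s' would make an element count negative", s))
    }
  }
  parse_formula(full[full > 0])
}
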