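# The lipid registry is data, not code: a TSV of species names, formulas,
# series derivations and declared nominal masses. The shipped default covers
# the brGDGT / OB-GDGT / brGMGT species routinely identified in anoxic
# water-column work; users supply their own TSV for other species sets.

#' Path to the default GDGT registry shipped with the package
#'
#' @return File path to the default registry TSV.
#' @export
default_registry_path <- function() {
  system.file("extdata", "gdgt_registry.tsv", package = "tetralink", mustWork = TRUE)
}

#' Read a lipid registry
#'
#' A registry is a TSV with columns `name`, `series_class`, `formula`,
#' `parent`, `steps` (comma-separated series steps applied to the parent)
#' and `nominal_mz` (the declared nominal \[M+H\]+ mass). Lines starting
#' with `#` are comments.
#'
#' @param path Registry TSV; defaults to the shipped GDGT registry.
#' @return A tibble, one row per lipid species.
#' @examples
#' read_lipid_registry()
#' @export
read_lipid_registry <- function(path = default_registry_path()) {
  reg <- read_tl_tsv(path, c("name", "series_class", "formula",
                             "parent", "steps", "nominal_mz"))
  if (anyDuplicated(reg$name)) {
    tl_abort(sprintf("duplicate lipid name(s) in registry: %s",
                     paste(unique(reg$name[duplicated(reg$name)]), collapse = ", ")))
  }
  reg$nominal_mz <- as.integer(reg$nominal_mz)
  reg
}

#' Check a lipid registry for mass and series consistency
#'
#' For every species, recomputes the rounded \[M+H\]+ m/z from its molecular
#' formula and, where a parent and series steps are declared, the formula
#' implied by applying those steps to the parent. Flags any species whose
#' computed nominal mass conflicts with the declared `nominal_mz`, or whose
#' formula is inconsistent with its series derivation.
#'
#' @param registry A registry tibble from [read_lipid_registry()].
#' @return The registry with columns `computed_mz`, `mz_conflict`,
#'   `series_conflict` added.
#' @export
check_lipid_registry <- function(registry = read_lipid_registry()) {
  check_columns(registry, c("name", "formula", "parent", "steps", "nominal_mz"),
                "lipid registry")
  computed <- purrr::map_int(registry$formula,
                             ~ round_mz(adduct_mz(.x, "M+H")))
  series_conflict <- purrr::pmap_lgl(
    registry[, c("formula", "parent", "steps")],
    function(formula, parent, steps) {
      if (is.na(parent) || !nzchar(parent)) return(FALSE)
      idx <- match(parent, registry$name)
      if (is.na(idx)) return(TRUE)
      step_vec <- strsplit(steps, ",", fixed = TRUE)[[1]]
      derived <- apply_series_step(registry$formula[idx], trimws(step_vec))
      format_formula(derived) != format_formula(formula)
    })
  registry %>%
    mutate(
      computed_mz = computed,
      mz_conflict = .data$computed_mz != .data$nominal_mz,
      series_conflict = series_conflict
    )
}
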