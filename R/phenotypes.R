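#' Adhesion-preference phenotypes
#'
#' A tumour cell's phenotype is its integer cell-to-cell adhesion preference:
#' the number of occupied Moore neighbours (0--7) the cell requires at a
#' destination site before it will move there. Preference 0 cells seek empty
#' surroundings and disperse as single cells; preference 7 cells are attracted
#' to densely populated neighbourhoods and stay aggregated.
#'
#' @param phenotype integer vector of adhesion preferences in `0:7`.
#'
#' @return `phenotype_category()` returns a factor with levels
#'   `low` (preferences 0--1), `middle` (2--5) and `high` (6--7).
#' @examples
#' phenotype_category(c(0, 4, 7))
#' @export
phenotype_category <- function(phenotype) {
  phenotype <- validate_phenotype(phenotype)
  cat <- dplyr::case_when(
    phenotype <= 1 ~ "low",
    phenotype <= 5 ~ "middle",
    TRUE ~ "high"
  )
  factor(cat, levels = c("low", "middle", "high"))
}

validate_phenotype <- function(phenotype, arg = "phenotype") {
  if (length(phenotype) == 0 || anyNA(phenotype) ||
      any(phenotype != round(phenotype)) ||
      any(phenotype < 0) || any(phenotype > 7)) {
    abort(sprintf("`%s` must be integers between 0 and 7 (adhesion preference).", arg),
          class = "gliomorph_invalid_phenotype")
  }
  as.integer(phenotype)
}
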