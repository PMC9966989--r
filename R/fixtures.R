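# Loaders for the published-values fixtures shipped under extdata: the
# reference oblique pattern matrix of the 29 items and the reference
# nutrient subgroup-mean table with its printed cut-offs.  These are
# *inputs* (printed values), used for worked examples and desk checks,
# not outputs of this package.

#' Reference oblique pattern matrix
#'
#' The published five-factor pattern solution of the 29 items (blank
#' cells as 0).  Used for item-assignment worked examples; the magnitudes
#' are not reproducible from synthetic data and are never asserted by the
#' analysis code.
#'
#' @return 29 x 5 matrix, rownames Q01..Q29, colnames ML1..ML5.
#' @export
reference_pattern <- function() {
  path <- system.file("extdata", "reference_pattern_matrix.csv",
                      package = "mhcscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$item
  m
}

#' Reference nutrient subgroup means and printed cut-offs
#'
#' The published per-subgroup mean intakes of the 17 selected nutrients
#' across the four MHC median splits, with the published Mann-Whitney
#' p-values and cut-off column.  Returned in the long `cells` layout used
#' by [feasible_interval()] and [validate_cutoff()].
#'
#' @return List with `cells` (data frame `nutrient`, `item`, `low_mean`,
#'   `high_mean`, `p_printed`) and `cutoffs_printed` (named numeric).
#' @export
reference_subgroup_means <- function() {
  path <- system.file("extdata", "reference_subgroup_means.csv",
                      package = "mhcscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- c(lov = "lack_of_vigor", irr = "irritability", fat = "fatigue",
           som = "somatic_symptoms")
  cells <- do.call(rbind, lapply(names(key), function(k) {
    data.frame(nutrient = df$nutrient, item = key[[k]],
               low_mean = df[[paste0(k, "_low")]],
               high_mean = df[[paste0(k, "_high")]],
               p_printed = df[[paste0(k, "_p")]],
               stringsAsFactors = FALSE)
  }))
  cells <- cells[order(match(cells$nutrient, df$nutrient)), ]
  rownames(cells) <- NULL
  list(cells = cells,
       cutoffs_printed = stats::setNames(df$cutoff_printed, df$nutrient))
}
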