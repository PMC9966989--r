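# Minor-health-complaint scores (four scales derived from the factor
# structure) and the cohort median split that defines low/high strata.

#' Score the four MHC scales
#'
#' Item sums of the raw 1--4 responses: lack of vigor (Q01--Q03, summed as
#' answered so higher = better status), irritability (Q04--Q06), fatigue
#' (Q07--Q09), somatic symptoms (Q19--Q26 and Q28).  Ranges are [3, 12],
#' [3, 12], [3, 12] and [9, 36].
#'
#' @param responses Data frame with `subject_id` and Q01..Q29, or a matrix.
#' @return Data frame `subject_id` plus the four integer scores.
#' @export
#' @examples
#' m <- matrix(1, 2, 29, dimnames = list(c("a", "b"), sprintf("Q%02d", 1:29)))
#' score_mhc(m)
score_mhc <- function(responses) {
  m <- likert_matrix(responses)
  sets <- mhc_items()
  out <- data.frame(subject_id = rownames(m), stringsAsFactors = FALSE)
  for (s in names(sets))
    out[[s]] <- as.integer(rowSums(m[, sets[[s]], drop = FALSE]))
  out
}

#' Median-split the cohort on each MHC scale
#'
#' For each scale the cohort median is computed (even-n median = midpoint
#' of the central order statistics) and each subject labelled `low`
#' (score <= median) or `high` (score > median).  Which label is the
#' better-status side differs by scale: for lack of vigor the high
#' subgroup is better; for the other three the low subgroup is better
#' (see [mhc_direction()]).
#'
#' @param scores Output of [score_mhc()].
#' @return Object of class `median_split`: `labels` (data frame
#'   `subject_id` + one low/high factor column per scale), `medians`
#'   (named numeric), `direction` (better-status label per scale).
#' @export
median_split <- function(scores) {
  scales <- names(mhc_direction())
  missing_cols <- setdiff(scales, names(scores))
  if (length(missing_cols))
    stop("validation error: scores lack columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(scores) < 2) stop("median split needs at least 2 subjects")
  labels <- data.frame(subject_id = scores$subject_id,
                       stringsAsFactors = FALSE)
  medians <- numeric(0)
  degenerate <- character(0)
  for (s in scales) {
    med <- stats::median(scores[[s]])
    medians[s] <- med
    lab <- ifelse(scores[[s]] > med, "high", "low")
    if (length(unique(lab)) < 2) degenerate <- c(degenerate, s)
    labels[[s]] <- lab
  }
  if (length(degenerate))
    stop("degenerate median split (one subgroup empty) for: ",
         paste(degenerate, collapse = ", "))
  structure(list(labels = labels, medians = medians,
                 direction = mhc_direction()),
            class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat("Median split of", nrow(x$labels), "subjects\n")
  for (s in names(x$medians))
    cat(sprintf("  %-18s median %5.1f  (%s = better status)\n",
                s, x$medians[s], x$direction[s]))
  invisible(x)
}
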