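# Nutrient screening: Mann-Whitney comparison of intakes between MHC
# median-split subgroups, the >=3-of-4 selection rule, feasible-interval
# cut-off derivation and validation, and nutrient-count stratification.

#' Mann-Whitney U test
#'
#' Two-sided test of identical distributions against a location shift.
#' For small samples (both sizes <= 8) the p-value is computed by exact
#' enumeration of all labellings of the combined sample (midranks for
#' ties); otherwise by the normal approximation with tie correction and a
#' continuity correction.  No multiple-testing adjustment is applied here.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 8).
#' @return List with `U` (statistic for `a`: number of (a, b) pairs with
#'   a > b, ties counted 1/2), `p` (two-sided), `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # exact enumeration over all choose(N, n1) labellings
    combos <- utils::combn(N, n1)
    stat <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(stat - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate (all tied)"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal approximation with tie correction")
}

#' Screen nutrients against the four MHC splits
#'
#' Every nutrient column is compared between the low and high subgroup of
#' each MHC scale by Mann-Whitney.  A nutrient is *selected* when its
#' p-value is below `alpha` on at least `min_items` of the four scales.
#' A caloric-intake column (`Energy_kcal`), if present, is tested and
#' reported but is never part of the selectable set.
#'
#' @param intakes Data frame `subject_id` + nutrient columns.
#' @param splits A [median_split()].
#' @param alpha Significance level (default 0.05, unadjusted: the screen
#'   runs 39 x 4 raw tests by design; see `bh` for an optional
#'   Benjamini-Hochberg variant).
#' @param min_items Minimum number of scales with p < alpha (default 3).
#' @param bh Apply Benjamini-Hochberg across all cells before selection
#'   (off by default; the reference procedure uses raw p-values).
#' @param require_panel Require all 39 panel nutrients (default TRUE).
#' @return Object of class `nutrient_screen`: `cells` (long data frame
#'   `nutrient`, `item`, `low_mean`, `high_mean`, `n_low`, `n_high`, `U`,
#'   `p`), `selected` (character vector), `alpha`, `n_tests`.
#' @export
screen_nutrients <- function(intakes, splits, alpha = 0.05, min_items = 3,
                             bh = FALSE, require_panel = TRUE) {
  stopifnot(inherits(splits, "median_split"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  nutrients <- setdiff(names(intakes), "subject_id")
  if (require_panel) {
    missing_cols <- setdiff(nutrient_panel()$nutrient, nutrients)
    if (length(missing_cols))
      stop("validation error: intake table lacks nutrient columns: ",
           paste(missing_cols, collapse = ", "))
  }
  lab <- splits$labels
  m <- merge(lab, intakes, by = "subject_id")
  if (nrow(m) < nrow(lab))
    warning("dropped ", nrow(lab) - nrow(m),
            " subjects without intake rows")
  scales <- names(mhc_direction())
  cells <- do.call(rbind, lapply(nutrients, function(nu) {
    do.call(rbind, lapply(scales, function(s) {
      lo <- m[[nu]][m[[s]] == "low"]
      hi <- m[[nu]][m[[s]] == "high"]
      mw <- mann_whitney(lo, hi)
      data.frame(nutrient = nu, item = s,
                 low_mean = mean(lo), high_mean = mean(hi),
                 n_low = length(lo), n_high = length(hi),
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(cells) <- NULL
  pj <- if (bh) stats::p.adjust(cells$p, "BH") else cells$p
  cells$significant <- pj < alpha
  selectable <- setdiff(nutrients, "Energy_kcal")
  hits <- tapply(cells$significant, cells$nutrient, sum)
  selected <- intersect(selectable, names(hits)[hits >= min_items])
  structure(list(cells = cells, selected = selected, alpha = alpha,
                 min_items = min_items, bh = bh,
                 n_tests = nrow(cells)),
            class = "nutrient_screen")
}

#' @export
print.nutrient_screen <- function(x, ...) {
  cat(sprintf(
    "Nutrient screen: %d tests (raw alpha = %g%s); %d nutrient(s) significant on >= %d of 4 scales:\n",
    x$n_tests, x$alpha, if (x$bh) ", BH-adjusted" else ", unadjusted",
    length(x$selected), x$min_items))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

orient_cells <- function(cells, direction = mhc_direction()) {
  worse <- ifelse(direction[cells$item] == "low",
                  cells$high_mean, cells$low_mean)
  better <- ifelse(direction[cells$item] == "low",
                   cells$low_mean, cells$high_mean)
  cbind(cells, worse_mean = worse, better_mean = better)
}

#' Feasible cut-off interval for one nutrient
#'
#' The interval between the largest worse-status subgroup mean and the
#' smallest better-status subgroup mean over the four MHC scales.  A
#' cut-off inside this interval is above every worse-status mean and below
#' every better-status mean.  The interval may be empty (`lo >= hi`);
#' emptiness is reported, not treated as an error.
#'
#' @param cells Rows of a screen `cells` table for a single nutrient
#'   (columns `item`, `low_mean`, `high_mean`).
#' @param direction Better-status label per scale
#'   (default [mhc_direction()]).
#' @return List `lo`, `hi`, `empty`, plus the oriented means.
#' @export
feasible_interval <- function(cells, direction = mhc_direction()) {
  if (length(unique(cells$nutrient)) > 1)
    stop("feasible_interval expects cells for a single nutrient")
  need <- names(direction)
  if (!setequal(cells$item, need))
    stop("need one row per MHC scale: ", paste(need, collapse = ", "))
  oc <- orient_cells(cells, direction)
  lo <- max(oc$worse_mean)
  hi <- min(oc$better_mean)
  list(lo = lo, hi = hi, empty = lo >= hi,
       worse_means = stats::setNames(oc$worse_mean, oc$item),
       better_means = stats::setNames(oc$better_mean, oc$item))
}

#' Derive a cut-off from a feasible interval
#'
#' Default rule: the interval midpoint rounded to two significant figures.
#' The rule is pluggable because the reference procedure never states its
#' rounding; the default reproduces several but not all published
#' cut-offs, and an empty interval yields `NA` (a manual override is then
#' required).
#'
#' @param interval Output of [feasible_interval()], or a length-2 numeric.
#' @param rule Function mapping `(lo, hi)` to a cut-off.
#' @return Cut-off value, or `NA_real_` for an empty interval.
#' @export
#' @examples
#' derive_cutoff(list(lo = 2441.6, hi = 2507.0, empty = FALSE))  # 2500
derive_cutoff <- function(interval,
                          rule = function(lo, hi) signif((lo + hi) / 2, 2)) {
  if (is.numeric(interval) && length(interval) == 2)
    interval <- list(lo = interval[1], hi = interval[2],
                     empty = interval[1] >= interval[2])
  if (isTRUE(interval$empty)) return(NA_real_)
  rule(interval$lo, interval$hi)
}

#' Validate a cut-off against subgroup means
#'
#' Lists every (scale, bound) where the separation requirement fails: a
#' worse-status mean at or above the cut-off, or a better-status mean at
#' or below it.
#'
#' @param cutoff Candidate cut-off.
#' @param cells Screen cells for one nutrient.
#' @param direction Better-status label per scale.
#' @return Data frame of violations (possibly empty) with columns `item`,
#'   `bound` (`"lower"`/`"upper"`), `mean`.
#' @export
validate_cutoff <- function(cutoff, cells, direction = mhc_direction()) {
  oc <- orient_cells(cells, direction)
  v <- rbind(
    data.frame(item = oc$item, bound = "lower", mean = oc$worse_mean,
               stringsAsFactors = FALSE)[oc$worse_mean >= cutoff, ],
    data.frame(item = oc$item, bound = "upper", mean = oc$better_mean,
               stringsAsFactors = FALSE)[oc$better_mean <= cutoff, ]
  )
  rownames(v) <- NULL
  v
}

#' Derive (and validate) cut-offs for a selected nutrient set
#'
#' @param screen A `nutrient_screen`.
#' @param nutrients Which nutrients (default the screen's selected set).
#' @param overrides Named numeric vector of manual cut-offs taking
#'   precedence over the derived rule.
#' @param rule Passed to [derive_cutoff()].
#' @return Data frame `nutrient`, `lo`, `hi`, `empty`, `cutoff`, `source`
#'   (`derived`/`override`/`undefined`), `n_violations`.
#' @export
derive_cutoffs <- function(screen, nutrients = screen$selected,
                           overrides = NULL,
                           rule = function(lo, hi) signif((lo + hi) / 2, 2)) {
  out <- do.call(rbind, lapply(nutrients, function(nu) {
    cells <- screen$cells[screen$cells$nutrient == nu, ]
    iv <- feasible_interval(cells)
    if (!is.null(overrides) && nu %in% names(overrides)) {
      cutoff <- overrides[[nu]]; source <- "override"
    } else {
      cutoff <- derive_cutoff(iv, rule)
      source <- if (is.na(cutoff)) "undefined" else "derived"
    }
    nv <- if (is.na(cutoff)) NA_integer_
          else nrow(validate_cutoff(cutoff, cells))
    data.frame(nutrient = nu, lo = iv$lo, hi = iv$hi, empty = iv$empty,
               cutoff = cutoff, source = source, n_violations = nv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

ncount_bins <- function() {
  data.frame(label = c("0N", "1-4N", "5-8N", "9-12N", "13-17N"),
             lo = c(0L, 1L, 5L, 9L, 13L), hi = c(0L, 4L, 8L, 12L, 17L),
             stringsAsFactors = FALSE)
}

#' Stratify subjects by nutrient count and compare MHC levels
#'
#' Counts, per subject, how many selected nutrients are consumed *at or
#' above* their cut-off (>=; the counting rule of the reference
#' procedure), bins the count into the groups 0 / 1--4 / 5--8 / 9--12 /
#' 13--17, and compares each group's MHC scores against the 0N control
#' group by Mann-Whitney.
#'
#' @param intakes Data frame `subject_id` + nutrient columns.
#' @param cutoffs Named numeric vector of cut-offs (NA entries dropped
#'   with a warning), or the output of [derive_cutoffs()].
#' @param mhc_scores Output of [score_mhc()].
#' @param alpha Significance level for the group contrasts (default 0.05).
#' @return Object of class `ncount_result`: `groups` (subject_id, count,
#'   group), `summary` (group x scale: n, mean, se, p_vs_0N), `cutoffs`
#'   used, `alpha`.
#' @export
stratify_and_compare <- function(intakes, cutoffs, mhc_scores,
                                 alpha = 0.05) {
  if (is.data.frame(cutoffs))
    cutoffs <- stats::setNames(cutoffs$cutoff, cutoffs$nutrient)
  if (anyNA(cutoffs)) {
    warning("dropping nutrient(s) with undefined cut-off: ",
            paste(names(cutoffs)[is.na(cutoffs)], collapse = ", "))
    cutoffs <- cutoffs[!is.na(cutoffs)]
  }
  if (length(cutoffs) == 0) stop("no usable cut-offs")
  missing_cols <- setdiff(names(cutoffs), names(intakes))
  if (length(missing_cols))
    stop("validation error: intake table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  im <- as.matrix(intakes[, names(cutoffs), drop = FALSE])
  count <- as.integer(rowSums(im >= rep(cutoffs, each = nrow(im))))
  bins <- ncount_bins()
  if (max(count) > max(bins$hi))
    stop("nutrient count ", max(count), " exceeds the 13-17N bin; ",
         "the binning scheme assumes at most 17 selected nutrients")
  group <- vapply(count, function(ct)
    bins$label[bins$lo <= ct & ct <= bins$hi], character(1))
  groups <- data.frame(subject_id = intakes$subject_id, count = count,
                       group = factor(group, levels = bins$label),
                       stringsAsFactors = FALSE)
  m <- merge(groups, mhc_scores, by = "subject_id")
  scales <- names(mhc_direction())
  summary <- do.call(rbind, lapply(bins$label, function(g) {
    do.call(rbind, lapply(scales, function(s) {
      x <- m[[s]][m$group == g]
      ctrl <- m[[s]][m$group == "0N"]
      p <- if (g == "0N" || length(x) == 0 || length(ctrl) == 0) NA_real_
           else mann_whitney(x, ctrl)$p
      data.frame(group = g, item = s, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 se = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                      else NA_real_,
                 p_vs_0N = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  if (sum(groups$group == "0N") == 0)
    warning("empty 0N control group; group contrasts skipped")
  structure(list(groups = groups, summary = summary, cutoffs = cutoffs,
                 alpha = alpha),
            class = "ncount_result")
}

#' @export
print.ncount_result <- function(x, ...) {
  cat("Nutrient-count stratification (", length(x$cutoffs),
      " cut-offs )\n", sep = "")
  print(table(x$groups$group))
  invisible(x)
}
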