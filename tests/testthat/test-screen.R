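# Nutrient screen: Mann-Whitney machinery, selection rule, feasible
# intervals, cut-offs, nutrient-count stratification.

test_that("identical samples give U = n^2/2 and p ~ 1", {
  x <- c(1, 2, 2, 3, 5)
  mw <- mann_whitney(x, x)
  expect_equal(mw$U, length(x)^2 / 2)
  expect_gte(mw$p, 0.99)
  big <- rep(c(1, 2, 3), 40)
  expect_gte(mann_whitney(big, big)$p, 0.99)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("fully separated triples give exact two-sided p = 0.1", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                 # 2 of the 20 labelings
  expect_match(mw$method, "exact")
})

test_that("exact path agrees with the reference implementation without ties", {
  set.seed(71)
  for (rep in 1:8) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.6)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal-approximation path agrees with the reference implementation", {
  set.seed(72)
  for (rep in 1:6) {
    a <- round(rnorm(40, 0, 2), 1)        # rounded -> ties
    b <- round(rnorm(55, 0.5, 2), 1)
    expect_equal(mann_whitney(a, b)$p,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("shifted normals at the cohort's group sizes are almost always detected", {
  set.seed(73)
  hits <- 0
  for (r in 1:100) {
    a <- rnorm(397); b <- rnorm(397, 0.5)
    hits <- hits + (mann_whitney(a, b)$p < 0.05)
  }
  expect_gte(hits / 100, 0.99)
})

test_that("screen selects planted nutrients and respects alpha semantics", {
  fx <- default_cohort_fixture()
  sp <- median_split(score_mhc(fx$responses))
  scr <- screen_nutrients(fx$nutrients, sp)
  expect_equal(nrow(scr$cells), 39 * 4)
  expect_true(all(scr$cells$p >= 0 & scr$cells$p <= 1))
  expect_true(all(scr$cells$low_mean > 0 & scr$cells$high_mean > 0))
  planted <- nutrient_panel()$nutrient[nutrient_panel()$planted]
  expect_setequal(scr$selected, planted)
  # vacuous threshold selects everything
  scr1 <- screen_nutrients(fx$nutrients, sp, alpha = 1)
  expect_setequal(scr1$selected, nutrient_panel()$nutrient)
  # monotone in alpha
  for (al in c(0.01, 0.05, 0.2)) {
    s_lo <- screen_nutrients(fx$nutrients, sp, alpha = al)$selected
    s_hi <- screen_nutrients(fx$nutrients, sp,
                             alpha = min(1, al * 4))$selected
    expect_true(all(s_lo %in% s_hi))
  }
})

test_that("caloric intake is tested but never selectable", {
  fx <- default_cohort_fixture()
  sp <- median_split(score_mhc(fx$responses))
  nut <- fx$nutrients
  # make energy blatantly associated by construction
  nut$Energy_kcal <- nut$K_mg + nut$Mg_mg * 10
  scr <- screen_nutrients(nut, sp)
  expect_true("Energy_kcal" %in% scr$cells$nutrient)
  expect_true(sum(scr$cells$nutrient == "Energy_kcal" &
                    scr$cells$significant) >= 3)
  expect_false("Energy_kcal" %in% scr$selected)
})

test_that("a missing nutrient column is a validation error", {
  fx <- default_cohort_fixture()
  sp <- median_split(score_mhc(fx$responses))
  expect_error(screen_nutrients(fx$nutrients[, -2], sp),
               "lacks nutrient columns")
})

test_that("feasible intervals match the printed worked examples", {
  ref <- reference_subgroup_means()
  k <- feasible_interval(ref$cells[ref$cells$nutrient == "K_mg", ])
  expect_equal(c(k$lo, k$hi), c(2441.6, 2507.0))
  expect_false(k$empty)
  mg <- feasible_interval(ref$cells[ref$cells$nutrient == "Mg_mg", ])
  expect_equal(c(mg$lo, mg$hi), c(265.8, 274.4))
  va <- feasible_interval(ref$cells[ref$cells$nutrient == "VA_ugRE", ])
  expect_true(va$empty)                  # better mean below worse mean
  expect_equal(unname(va$hi), 564.1)
})

test_that("feasible interval is permutation invariant and matches a min/max oracle", {
  ref <- reference_subgroup_means()
  cells <- ref$cells[ref$cells$nutrient == "TDF_g", ]
  iv1 <- feasible_interval(cells)
  iv2 <- feasible_interval(cells[sample(4), ])
  expect_equal(iv1[c("lo", "hi")], iv2[c("lo", "hi")])
  # brute-force oracle over the 8 means with explicit orientation
  dirn <- mhc_direction()
  worse <- better <- numeric(0)
  for (r in seq_len(4)) {
    lm <- cells$low_mean[r]; hm <- cells$high_mean[r]
    if (dirn[[cells$item[r]]] == "low") {
      worse <- c(worse, hm); better <- c(better, lm)
    } else {
      worse <- c(worse, lm); better <- c(better, hm)
    }
  }
  expect_equal(iv1$lo, max(worse))
  expect_equal(iv1$hi, min(better))
})

test_that("default cut-off rule reproduces the printed K / TDF / FA values", {
  ref <- reference_subgroup_means()
  cutoff_of <- function(nu) derive_cutoff(
    feasible_interval(ref$cells[ref$cells$nutrient == nu, ]))
  expect_equal(cutoff_of("K_mg"), 2500)
  expect_equal(cutoff_of("TDF_g"), 18)
  expect_equal(cutoff_of("FA_ug"), 300)
  # degenerate sliver: midpoint stays inside before rounding
  expect_equal(derive_cutoff(list(lo = 5, hi = 5 + 1e-6, empty = FALSE),
                             rule = function(lo, hi) (lo + hi) / 2),
               5 + 5e-7)
  expect_true(is.na(derive_cutoff(list(lo = 2, hi = 1, empty = TRUE))))
})

test_that("cut-off validation flags the printed iron inconsistency", {
  ref <- reference_subgroup_means()
  fe <- ref$cells[ref$cells$nutrient == "Fe_mg", ]
  v <- validate_cutoff(8.1, fe)
  expect_equal(nrow(v), 1)
  expect_equal(v$item, "somatic_symptoms")
  expect_equal(v$bound, "lower")
  expect_equal(v$mean, 8.16)             # worse-status mean >= 8.1
  # potassium's printed cut-off separates cleanly
  kk <- ref$cells[ref$cells$nutrient == "K_mg", ]
  expect_equal(nrow(validate_cutoff(2500, kk)), 0)
  # a cut-off below all eight means: 4 lower violations, 0 upper
  v2 <- validate_cutoff(0, kk)
  expect_equal(sum(v2$bound == "lower"), 4)
  expect_equal(sum(v2$bound == "upper"), 0)
})

test_that("counting uses >= at the cut-off and bins as printed", {
  intakes <- data.frame(subject_id = c("a", "b", "c"),
                        X1 = c(10, 9.99, 0), X2 = c(5, 5, 0))
  cuts <- c(X1 = 10, X2 = 5)
  scores <- data.frame(subject_id = c("a", "b", "c"),
                       lack_of_vigor = c(9L, 6L, 3L),
                       irritability = c(3L, 6L, 9L),
                       fatigue = c(3L, 6L, 9L),
                       somatic_symptoms = c(9L, 15L, 30L))
  st <- stratify_and_compare(intakes, cuts, scores)
  expect_equal(st$groups$count, c(2L, 1L, 0L))  # subject a at both cut-offs
  expect_equal(as.character(st$groups$group), c("1-4N", "1-4N", "0N"))
})

test_that("all subjects below all cut-offs collapse into 0N", {
  intakes <- data.frame(subject_id = c("a", "b"), X1 = c(1, 2))
  scores <- data.frame(subject_id = c("a", "b"),
                       lack_of_vigor = c(5L, 9L), irritability = c(5L, 7L),
                       fatigue = c(5L, 7L), somatic_symptoms = c(12L, 20L))
  st <- stratify_and_compare(intakes, c(X1 = 100), scores)
  expect_true(all(st$groups$group == "0N"))
  expect_true(all(is.na(st$summary$p_vs_0N)))
})

test_that("count is the sum of per-nutrient indicators and labels are pure functions of count", {
  fx <- default_cohort_fixture()
  sp <- median_split(score_mhc(fx$responses))
  scr <- screen_nutrients(fx$nutrients, sp)
  cut <- derive_cutoffs(scr)
  st <- stratify_and_compare(fx$nutrients, cut, score_mhc(fx$responses))
  cuts <- setNames(cut$cutoff, cut$nutrient)
  manual <- rowSums(sapply(names(cuts), function(nu)
    fx$nutrients[[nu]] >= cuts[[nu]]))
  expect_equal(st$groups$count, as.integer(manual))
  bins <- data.frame(lo = c(0, 1, 5, 9, 13), hi = c(0, 4, 8, 12, 17),
                     label = c("0N", "1-4N", "5-8N", "9-12N", "13-17N"))
  lab <- bins$label[findInterval(st$groups$count, bins$lo)]
  expect_equal(as.character(st$groups$group), lab)
})

test_that("default cohort stratification mirrors the published contrast pattern", {
  fx <- default_cohort_fixture()
  scores <- score_mhc(fx$responses)
  sp <- median_split(scores)
  scr <- screen_nutrients(fx$nutrients, sp)
  cut <- derive_cutoffs(scr)
  st <- stratify_and_compare(fx$nutrients, cut, scores)
  lov <- st$summary[st$summary$item == "lack_of_vigor", ]
  lov <- lov[match(c("0N", "1-4N", "5-8N", "9-12N", "13-17N"), lov$group), ]
  # vigor is higher-is-better: means non-decreasing with nutrient count
  expect_true(all(diff(lov$mean) >= -1e-9))
  # the three upper groups differ from the 0N control
  expect_true(all(lov$p_vs_0N[3:5] < 0.05))
})
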