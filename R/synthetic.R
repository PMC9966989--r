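# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: five
# correlated latent psychosomatic traits drive ordinal item responses
# through a graded mechanism whose dichotomisation is exactly a 2PL item,
# and nutrient intakes are log-normal with an optional planted mean shift
# between the better- and worse-status halves of the latent MHC burden.

#' Run an expression with a private RNG seed
#'
#' Saves and restores the global RNG state so that generator calls are
#' deterministic without clobbering the caller's random stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default pattern loadings of the five-factor structure
#'
#' 29 x 5 matrix of standardized loadings with the block structure of the
#' five retained factors (anxiety--depression, lack of vigor, irritability,
#' fatigue, somatic symptoms).  Magnitudes mirror a published oblique
#' pattern solution for this instrument; each item loads on exactly one
#' factor by default.
#'
#' @return 29 x 5 numeric matrix, rownames Q01..Q29.
#' @export
default_loadings <- function() {
  instr <- bjsq_instrument()
  fac <- names(mhc_factors())
  lambda <- c(0.86, 0.88, 0.91,            # Q01-Q03 lack of vigor
              0.86, 0.87, 0.70,            # Q04-Q06 irritability
              0.81, 0.84, 0.52,            # Q07-Q09 fatigue
              0.36, 0.74, 0.65,            # Q10-Q12 anxiety
              0.71, 0.42, 0.57, 0.69, 0.62, 0.59,  # Q13-Q18 depressed mood
              0.34, 0.41, 0.52, 0.60, 0.54, 0.50, 0.34, 0.32,  # Q19-Q26
              0.32,                        # Q27 -> anxiety--depression
              0.32,                        # Q28 -> somatic
              0.29)                        # Q29 -> anxiety--depression
  L <- matrix(0, 29, 5, dimnames = list(instr$item, fac))
  for (i in seq_len(29)) L[i, instr$factor[i]] <- lambda[i]
  L
}

#' Default graded-response thresholds
#'
#' Three ordered cut points per item on the latent-trait (IRT difficulty)
#' scale.  The middle cut is the 2PL difficulty of the dichotomised item;
#' the factor-level defaults are calibrated so that vigor complaints emerge
#' earliest (lowest difficulty), fatigue and irritability next, anxiety and
#' depressed mood last, and somatic items are dispersed over a broad range
#' of the trait.
#'
#' @param spread Distance between adjacent cut points (default 1.2).
#' @return 29 x 3 numeric matrix, rownames Q01..Q29.
#' @export
default_thresholds <- function(spread = 1.2) {
  instr <- bjsq_instrument()
  mid <- numeric(29)
  names(mid) <- instr$item
  mid[instr$factor == "lack_of_vigor"] <- -0.7
  mid[instr$factor == "irritability"] <- 0.0
  mid[instr$factor == "fatigue"] <- -0.1
  mid[instr$factor == "anxiety_depression"] <- 0.8
  som <- instr$item[instr$factor == "somatic_symptoms"]
  mid[som] <- seq(-2, 2, length.out = length(som))
  cbind(b1 = mid - spread, b2 = mid, b3 = mid + spread)
}

#' Default factor correlation matrix
#'
#' Uniform moderate correlation (0.5) among the five psychosomatic traits,
#' consistent with the strongly inter-correlated stress-reaction scales of
#' this instrument.
#' @return 5 x 5 correlation matrix.
#' @export
default_factor_correlations <- function() {
  fac <- names(mhc_factors())
  m <- matrix(0.5, 5, 5, dimnames = list(fac, fac))
  diag(m) <- 1
  m
}

#' Default planted nutrient effects
#'
#' Standardized mean shift (log scale) between the better- and worse-status
#' latent strata for each of the 39 nutrients: 17 nutrients carry a nonzero
#' shift by default, the remaining 22 are null.
#'
#' @param effect Shift for the planted nutrients (default 0.8 standard
#'   deviations of log intake).
#' @return Named numeric vector of length 39.
#' @export
default_nutrient_effects <- function(effect = 0.8) {
  panel <- nutrient_panel()
  stats::setNames(ifelse(panel$planted, effect, 0), panel$nutrient)
}

#' Default nutrient location/scale parameters
#'
#' @param sdlog Standard deviation of log intake (default 0.35, a typical
#'   coefficient of variation for daily nutrient intake).
#' @return Data frame with columns `nutrient`, `location`, `sdlog`.
#' @export
default_nutrient_base <- function(sdlog = 0.35) {
  panel <- nutrient_panel()
  data.frame(nutrient = panel$nutrient, location = panel$location,
             sdlog = sdlog, stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort generator configuration
#'
#' @param n_subjects Number of records to generate (before exclusions).
#' @param seed Integer seed; all randomness flows from it.
#' @param factor_correlations 5 x 5 symmetric positive semi-definite matrix
#'   with unit diagonal.
#' @param item_loadings 29 x 5 loading matrix (see [default_loadings()]).
#' @param graded_thresholds 29 x 3 matrix of strictly increasing cut points
#'   per item (see [default_thresholds()]).
#' @param nutrient_effects Named length-39 vector of standardized log-scale
#'   mean shifts between latent strata.
#' @param nutrient_base Data frame `nutrient`/`location`/`sdlog` with
#'   positive locations and scales.
#' @param exclusion_counts Named integer vector
#'   `c(non_worker = , high_stress = )`: how many records to flag for each
#'   exclusion reason (disjoint sets).
#' @param diet_correlation Cross-nutrient diet-quality correlation share
#'   (see [generate_nutrients()]).
#' @return Object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$subjects)
generator_config <- function(n_subjects = 887,
                             seed = 20230208,
                             factor_correlations = default_factor_correlations(),
                             item_loadings = default_loadings(),
                             graded_thresholds = default_thresholds(),
                             nutrient_effects = default_nutrient_effects(),
                             nutrient_base = default_nutrient_base(),
                             exclusion_counts = c(non_worker = 75,
                                                  high_stress = 18),
                             diet_correlation = 0.5) {
  cfg <- list(n_subjects = n_subjects, seed = seed,
              factor_correlations = factor_correlations,
              item_loadings = item_loadings,
              graded_thresholds = graded_thresholds,
              nutrient_effects = nutrient_effects,
              nutrient_base = nutrient_base,
              exclusion_counts = exclusion_counts,
              diet_correlation = diet_correlation)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 0 || cfg$n_subjects != round(cfg$n_subjects))
    stop("configuration error: n_subjects must be a non-negative integer")
  fc <- cfg$factor_correlations
  if (!is.matrix(fc) || nrow(fc) != 5 || ncol(fc) != 5 ||
      max(abs(fc - t(fc))) > 1e-8 || any(abs(diag(fc) - 1) > 1e-8))
    stop("configuration error: factor_correlations must be a symmetric 5x5 matrix with unit diagonal")
  if (min(eigen(fc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("configuration error: factor_correlations is not positive semi-definite")
  th <- cfg$graded_thresholds
  if (!is.matrix(th) || ncol(th) != 3)
    stop("configuration error: graded_thresholds must have 3 columns")
  if (any(th[, 2] <= th[, 1]) || any(th[, 3] <= th[, 2]))
    stop("configuration error: graded_thresholds must be strictly increasing per item")
  if (!is.matrix(cfg$item_loadings) ||
      nrow(cfg$item_loadings) != nrow(th))
    stop("configuration error: item_loadings and graded_thresholds disagree on item count")
  base <- cfg$nutrient_base
  if (any(base$location <= 0) || any(base$sdlog <= 0))
    stop("configuration error: nutrient_base location and sdlog must be positive")
  eff <- cfg$nutrient_effects
  if (is.null(names(eff)) || !all(names(eff) %in% base$nutrient))
    stop("configuration error: nutrient_effects must be named after nutrient_base nutrients")
  exc <- cfg$exclusion_counts
  if (any(exc < 0))
    stop("configuration error: exclusion counts must be non-negative")
  if (sum(exc) > cfg$n_subjects)
    stop("configuration error: exclusion counts exceed n_subjects")
  invisible(cfg)
}

#' Map a standardized loading to a 2PL discrimination
#'
#' Normal-ogive relation with the conventional logistic scaling constant:
#' `a = 1.702 * lambda / sqrt(1 - lambda^2)`.
#' @param lambda Standardized loading in `[0, 1)`.
#' @return Discrimination on the logistic scale.
#' @export
loading_to_discrimination <- function(lambda) {
  1.702 * lambda / sqrt(pmax(1 - lambda^2, 1e-12))
}

# Latent loading that realises a target point-biserial (Pearson) loading
# on the dichotomised item.  Dichotomising a latent-response item with
# latent loading l* and difficulty b attenuates the observed correlation
# to l* dnorm(l* b) / sqrt(p (1 - p)) with p = pnorm(-l* b); the
# configured loadings are targets on the analysis metric (Pearson of the
# recoded 0/1 items), so we invert that relation.  Targets beyond the
# attainable maximum (possible for loadings around 0.9) are capped.
latent_loading <- function(target, b, cap = 0.95) {
  if (target <= 0) return(0)
  g <- function(l) {
    p <- stats::pnorm(-l * b)
    l * stats::dnorm(l * b) / sqrt(pmax(p * (1 - p), 1e-12)) - target
  }
  if (g(cap) < 0) return(cap)
  stats::uniroot(g, c(1e-9, cap), tol = 1e-9)$root
}

#' Generate ordinal item responses from latent traits
#'
#' Graded mechanism: for item *j* with loading row `L[j, ]`, the item trait
#' is the unit combination `eta = theta %*% L[j, ] / ||L[j, ]||` and
#' `P(Y >= k + 1 | eta) = plogis(a_j (eta - b_jk))` for the three ordered
#' cut points `b_jk`.  Collapsing categories \{3, 4\} therefore yields a
#' logistic 2PL item with difficulty `b_j2`, which is what the downstream
#' IRT stage assumes.  Reverse-keyed items are flipped (`5 - category`) so
#' that for every item a response toward the unfavourable pole becomes more
#' likely as the trait grows.
#'
#' The configured loading `||L[j, ]||` is a target on the *analysis*
#' metric -- the Pearson loading of the dichotomised item.  Because
#' dichotomisation attenuates correlations, the generator solves for the
#' latent discrimination that realises the target after recoding
#' (capped near 0.95 where a target is unattainable, which happens for
#' loadings around 0.9); difficulties are not affected.
#'
#' @param theta n x k matrix of latent traits (higher = worse status).
#' @param loadings p x k loading matrix (targets on the recoded-item
#'   Pearson metric).
#' @param thresholds p x 3 matrix of strictly increasing cut points.
#' @param reverse Logical vector of length p; defaults to the instrument's
#'   reverse flags when p = 29, otherwise all `FALSE`.
#' @return n x p integer matrix with values in 1..4, columns named after
#'   the loading rownames.
#' @export
generate_responses <- function(theta, loadings, thresholds, reverse = NULL) {
  theta <- as.matrix(theta)
  loadings <- as.matrix(loadings)
  thresholds <- as.matrix(thresholds)
  if (ncol(theta) != ncol(loadings))
    stop("dimension mismatch: theta has ", ncol(theta),
         " columns but loadings has ", ncol(loadings))
  if (nrow(loadings) != nrow(thresholds))
    stop("dimension mismatch: loadings and thresholds disagree on item count")
  if (any(thresholds[, 2] <= thresholds[, 1]) ||
      any(thresholds[, 3] <= thresholds[, 2]))
    stop("thresholds must be strictly increasing per item")
  p <- nrow(loadings)
  n <- nrow(theta)
  if (is.null(reverse)) {
    reverse <- if (p == 29) bjsq_instrument()$reverse else rep(FALSE, p)
  }
  out <- matrix(1L, n, p)
  colnames(out) <- rownames(loadings)
  if (n == 0) return(out)
  for (j in seq_len(p)) {
    lj <- loadings[j, ]
    norm <- sqrt(sum(lj^2))
    if (norm > 0) {
      eta <- as.vector(theta %*% (lj / norm))
      lstar <- latent_loading(min(norm, 0.999), thresholds[j, 2])
      a <- loading_to_discrimination(lstar)
    } else {
      eta <- rep(0, n)
      a <- 0
    }
    u <- stats::runif(n)
    cat <- rep(1L, n)
    for (k in 1:3) {
      pk <- stats::plogis(a * (eta - thresholds[j, k]))
      cat <- cat + as.integer(u < pk)
    }
    if (reverse[j]) cat <- 5L - cat
    out[, j] <- cat
  }
  out
}

#' Generate nutrient intakes coupled to latent MHC burden
#'
#' Intakes are log-normal with mean `location` (the log-location is
#' `log(location) - sdlog^2 / 2`).  Nutrients share a per-subject diet
#' quality factor (`diet_correlation` of the log-scale standard
#' deviation), emulating the strong cross-nutrient correlation of real
#' food-pattern data; without it, nutrient-count strata (0N .. 13-17N)
#' would be nearly empty at the extremes.  The cohort is split at the
#' median of the mean MHC latent burden (mean of the four MHC traits,
#' higher = worse); for a nutrient with planted standardized shift `d`,
#' subjects in the better-status half receive `+d * sdlog / 2` on the log
#' scale and the worse half `-d * sdlog / 2`, so the better stratum's mean
#' intake exceeds the worse stratum's by approximately
#' `d * sdlog * location`.
#'
#' @param mhc_latent n x 4 matrix of the four MHC latent traits.
#' @param effects Named vector of standardized shifts (see
#'   [default_nutrient_effects()]).
#' @param base Data frame `nutrient`/`location`/`sdlog` (see
#'   [default_nutrient_base()]).
#' @param diet_correlation Share of log-scale standard deviation carried
#'   by the common diet-quality factor, in `[0, 1)` (default 0.5).
#' @return n x length(effects) matrix of strictly positive intakes.
#' @export
generate_nutrients <- function(mhc_latent,
                               effects = default_nutrient_effects(),
                               base = default_nutrient_base(),
                               diet_correlation = 0.5) {
  mhc_latent <- as.matrix(mhc_latent)
  if (any(base$location <= 0) || any(base$sdlog <= 0))
    stop("configuration error: nutrient locations and scales must be positive")
  if (diet_correlation < 0 || diet_correlation >= 1)
    stop("configuration error: diet_correlation must be in [0, 1)")
  base <- base[match(names(effects), base$nutrient), , drop = FALSE]
  if (anyNA(base$nutrient))
    stop("configuration error: effects name a nutrient missing from base")
  n <- nrow(mhc_latent)
  out <- matrix(numeric(0), n, length(effects),
                dimnames = list(NULL, names(effects)))
  if (n == 0) return(out)
  burden <- rowMeans(mhc_latent)
  worse <- burden > stats::median(burden)
  sign_shift <- ifelse(worse, -0.5, 0.5)
  diet <- stats::rnorm(n)
  rho <- diet_correlation
  for (j in seq_along(effects)) {
    s <- base$sdlog[j]
    mu <- log(base$location[j]) - s^2 / 2
    z <- rho * diet + sqrt(1 - rho^2) * stats::rnorm(n)
    out[, j] <- exp(mu + s * z + effects[j] * s * sign_shift)
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Produces the three tables of the analysis (subjects, questionnaire
#' responses, nutrient intakes), keyed by subject id, together with the
#' generating latent traits.  Exclusion flags (non-worker, sustained high
#' stress) are planted on randomly chosen disjoint subject sets according
#' to `config$exclusion_counts`, mirroring the published exclusion flow.
#'
#' @param config A [generator_config()].
#' @return List of class `cohort` with elements `subjects`, `responses`
#'   (data frame `subject_id` + Q01..Q29), `nutrients` (data frame
#'   `subject_id` + 39 intake columns), and `theta` (latent traits, for
#'   diagnostics only).  Same seed, same output.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n_subjects
  instr <- bjsq_instrument()
  fac <- colnames(config$factor_correlations)
  if (is.null(fac)) fac <- names(mhc_factors())
  with_seed(config$seed, {
    ids <- sprintf("S%05d", seq_len(n))
    # latent traits: MVN with the configured correlation
    ev <- eigen(config$factor_correlations, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 5) %*% t(ev$vectors)
    theta <- matrix(stats::rnorm(n * 5), n, 5) %*% rt
    colnames(theta) <- fac
    responses <- generate_responses(theta, config$item_loadings,
                                    config$graded_thresholds,
                                    reverse = instr$reverse)
    mhc_fac <- setdiff(fac, "anxiety_depression")
    nutrients <- generate_nutrients(theta[, mhc_fac, drop = FALSE],
                                    config$nutrient_effects,
                                    config$nutrient_base,
                                    config$diet_correlation)
    age_levels <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70+")
    age_prob <- c(0.053, 0.149, 0.292, 0.330, 0.146, 0.030)
    subjects <- data.frame(
      subject_id = ids,
      sex = if (n > 0) sample(c("male", "female"), n, TRUE, c(0.3, 0.7))
            else character(0),
      age_group = if (n > 0) sample(age_levels, n, TRUE, age_prob)
                  else character(0),
      fiscal_year = if (n > 0) sample(c(2019L, 2020L), n, TRUE,
                                      c(0.655, 0.345)) else integer(0),
      season = if (n > 0) sample(c("summer", "winter"), n, TRUE)
               else character(0),
      occupation_flag = rep(TRUE, n),
      high_stress_flag = rep(FALSE, n),
      stringsAsFactors = FALSE
    )
    exc <- config$exclusion_counts
    if (n > 0 && sum(exc) > 0) {
      flagged <- sample(ids, sum(exc))
      nw <- flagged[seq_len(exc[["non_worker"]])]
      hs <- setdiff(flagged, nw)
      subjects$occupation_flag[subjects$subject_id %in% nw] <- FALSE
      subjects$high_stress_flag[subjects$subject_id %in% hs] <- TRUE
    }
    responses <- data.frame(subject_id = ids, responses,
                            stringsAsFactors = FALSE, check.names = FALSE)
    nutrients <- data.frame(subject_id = ids, nutrients,
                            stringsAsFactors = FALSE, check.names = FALSE)
    structure(list(subjects = subjects, responses = responses,
                   nutrients = nutrients, theta = theta),
              class = "cohort")
  })
}

#' Write the three cohort tables as CSV
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             bjsq = file.path(dir, "bjsq.csv"),
             nutrients = file.path(dir, "nutrients.csv"))
  utils::write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE)
  utils::write.csv(cohort$responses, paths[["bjsq"]], row.names = FALSE)
  utils::write.csv(cohort$nutrients, paths[["nutrients"]], row.names = FALSE)
  invisible(paths)
}
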