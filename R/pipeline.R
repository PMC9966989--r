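# End-to-end driver: configuration, table validation, the staged pipeline
# (filter -> recode -> factor analysis -> IRT -> MHC -> nutrient screen ->
# cut-offs -> stratification), persistent CSV/JSON outputs and a run
# manifest.

#' Build a pipeline configuration
#'
#' @param subjects,bjsq,nutrients Paths to the three input CSVs (omit all
#'   three to run on a synthetic cohort generated in-memory).
#' @param output_dir Directory for stage outputs.
#' @param alpha Screening significance level.
#' @param n_factors Factor count; `NULL` lets parallel analysis decide.
#' @param assignment_threshold Loading cut for item assignment.
#' @param irt_quadrature,irt_tol Settings for the 2PL fits.
#' @param irt_joint Fit one joint trait for all items instead of
#'   per-factor traits.
#' @param cutoff_overrides Named numeric vector or path to a two-column
#'   CSV `nutrient,cutoff` of manual cut-offs.
#' @param seed Seed used for the synthetic cohort and parallel analysis.
#' @param n_subjects Synthetic cohort size when no input paths are given.
#' @param stages Character vector of stage names to run (default all).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects = NULL, bjsq = NULL, nutrients = NULL,
                            output_dir = "mhc_output", alpha = 0.05,
                            n_factors = 5, assignment_threshold = 0.29,
                            irt_quadrature = 21, irt_tol = 1e-4,
                            irt_joint = FALSE, cutoff_overrides = NULL,
                            seed = 20230208, n_subjects = 887,
                            stages = c("filter", "recode", "factors",
                                       "irt", "mhc", "screen", "cutoffs",
                                       "stratify")) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  cfg <- list(subjects = subjects, bjsq = bjsq, nutrients = nutrients,
              output_dir = output_dir, alpha = alpha,
              n_factors = n_factors,
              assignment_threshold = assignment_threshold,
              irt_quadrature = irt_quadrature, irt_tol = irt_tol,
              irt_joint = irt_joint, cutoff_overrides = cutoff_overrides,
              seed = seed, n_subjects = n_subjects, stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are a configuration error (named in the message).
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(raw$cutoff_overrides) &&
      is.list(raw$cutoff_overrides))
    raw$cutoff_overrides <- unlist(raw$cutoff_overrides)
  do.call(pipeline_config, raw)
}

#' Validate the three input tables
#'
#' Report-only checks: schema (required columns), ranges (Likert cells in
#' 1--4, strictly positive intakes), and key consistency (orphan ids in
#' either direction).  The pipeline driver decides whether to abort.
#'
#' @param subjects,bjsq,nutrients Data frames.
#' @return Data frame of problems (`table`, `kind`, `detail`); zero rows
#'   when everything is consistent.
#' @export
validate_tables <- function(subjects, bjsq, nutrients) {
  problems <- list()
  add <- function(tab, kind, detail)
    problems[[length(problems) + 1]] <<-
      data.frame(table = tab, kind = kind, detail = detail,
                 stringsAsFactors = FALSE)
  need_s <- c("subject_id", "occupation_flag", "high_stress_flag")
  for (cn in setdiff(need_s, names(subjects)))
    add("subjects", "schema", paste("missing column", cn))
  items <- bjsq_instrument()$item
  for (cn in setdiff(c("subject_id", items), names(bjsq)))
    add("bjsq", "schema", paste("missing column", cn))
  if (all(items %in% names(bjsq))) {
    m <- as.matrix(bjsq[, items])
    bad <- which(is.na(m) | m < 1 | m > 4 | m != round(m), arr.ind = TRUE)
    for (r in seq_len(min(nrow(bad), 20)))
      add("bjsq", "range",
          sprintf("value %s for subject %s item %s",
                  m[bad[r, 1], bad[r, 2]], bjsq$subject_id[bad[r, 1]],
                  items[bad[r, 2]]))
  }
  nun <- setdiff(names(nutrients), "subject_id")
  for (cn in nun) {
    x <- nutrients[[cn]]
    if (any(is.na(x) | x <= 0))
      add("nutrients", "range",
          sprintf("non-positive or missing %s for subject(s) %s", cn,
                  paste(utils::head(
                    nutrients$subject_id[is.na(x) | x <= 0], 5),
                    collapse = ", ")))
  }
  if ("subject_id" %in% names(subjects)) {
    for (tab in c("bjsq", "nutrients")) {
      df <- get(tab)
      if (!"subject_id" %in% names(df)) next
      orphan <- setdiff(df$subject_id, subjects$subject_id)
      for (o in utils::head(orphan, 20))
        add(tab, "orphan", paste("subject", o, "not in subjects table"))
    }
  }
  if (length(problems) == 0)
    return(data.frame(table = character(0), kind = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

read_inputs <- function(config) {
  if (is.null(config$subjects)) {
    cohort <- generate_cohort(generator_config(
      n_subjects = config$n_subjects, seed = config$seed))
    return(cohort[c("subjects", "responses", "nutrients")])
  }
  list(subjects = utils::read.csv(config$subjects,
                                  stringsAsFactors = FALSE),
       responses = utils::read.csv(config$bjsq, check.names = FALSE,
                                   stringsAsFactors = FALSE),
       nutrients = utils::read.csv(config$nutrients, check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the reference procedure: exclusion filter, binary
#' recode, factor count/EFA/CFA, per-factor 2PL IRT with thresholds, MHC
#' scoring and median split, nutrient screen, cut-off derivation, and
#' nutrient-count stratification.  All stage outputs are written under
#' `config$output_dir` together with a JSON run manifest; a rerun with the
#' same config and inputs reproduces the outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (invisibly contains all in-memory stage
#'   results as attribute `results`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- read_inputs(config)
  vr <- validate_tables(inputs$subjects, inputs$responses,
                        inputs$nutrients)
  if (nrow(vr) > 0) {
    utils::write.csv(vr, file.path(config$output_dir,
                                   "validation_report.csv"),
                     row.names = FALSE)
    stop("input validation failed at stage 'validate'; first problem: ",
         vr$table[1], " / ", vr$kind[1], ": ", vr$detail[1])
  }
  results <- list()
  manifest <- list(package_version =
                     as.character(utils::packageVersion("mhcscreen")),
                   seed = config$seed, alpha = config$alpha,
                   stages = list(), warnings = character(0))
  note <- function(stage, rows, extra = NULL)
    manifest$stages[[stage]] <<- c(list(rows = rows), extra)
  run <- function(s) s %in% config$stages

  included <- inputs$subjects$subject_id
  if (run("filter")) {
    flt <- filter_population(inputs$subjects)
    included <- flt$included
    results$filter <- flt
    jsonlite::write_json(
      c(as.list(flt$report), list(note = flt$note)),
      file.path(config$output_dir, "exclusion_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
    note("filter", length(included), list(report = as.list(flt$report)))
  }
  responses <- inputs$responses[inputs$responses$subject_id %in% included, ]
  nutrients <- inputs$nutrients[inputs$nutrients$subject_id %in% included, ]

  binary <- recode_binary(responses)
  if (run("recode")) {
    utils::write.csv(data.frame(subject_id = rownames(binary), binary,
                                check.names = FALSE),
                     file.path(config$output_dir, "binary.csv"),
                     row.names = FALSE)
    note("recode", nrow(binary))
  }

  assignment <- stats::setNames(bjsq_instrument()$factor,
                                bjsq_instrument()$item)
  if (run("factors")) {
    adequacy <- kmo(binary)
    counts <- count_factors(binary, seed = config$seed)
    k <- if (is.null(config$n_factors)) max(counts$parallel, 1)
         else config$n_factors
    sol <- withCallingHandlers(
      efa(binary, k),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    asg <- assign_items(sol, config$assignment_threshold)
    fit <- cfa_fit(binary, asg$assignment)
    assignment <- asg$assignment
    results$factors <- list(kmo = adequacy, counts = counts,
                            solution = sol, assignment = asg, cfa = fit)
    utils::write.csv(data.frame(item = rownames(sol$pattern),
                                round(sol$pattern, 4)),
                     file.path(config$output_dir, "efa_pattern.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(factor = rownames(sol$phi),
                                round(sol$phi, 4)),
                     file.path(config$output_dir, "efa_phi.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(kmo = adequacy, parallel = counts$parallel, map = counts$map,
           k = k, cfi = fit$cfi, tli = fit$tli, srmr = fit$srmr,
           chisq = fit$chisq, df = fit$df),
      file.path(config$output_dir, "factor_fit.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = 6)
    note("factors", nrow(sol$pattern),
         list(k = k, kmo = round(adequacy, 4)))
  }

  if (run("irt")) {
    fsets <- split(names(assignment)[!is.na(assignment)],
                   assignment[!is.na(assignment)])
    irt <- irt_thresholds(binary, fsets, joint = config$irt_joint,
                          quadrature = config$irt_quadrature,
                          tol = config$irt_tol)
    results$irt <- irt
    utils::write.csv(irt$params,
                     file.path(config$output_dir, "irt_params.csv"),
                     row.names = FALSE)
    curves <- data.frame(theta = irt$curves[[1]]$theta)
    for (f in names(irt$curves)) curves[[f]] <- irt$curves[[f]]$p
    utils::write.csv(curves,
                     file.path(config$output_dir, "irt_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(irt$thresholds),
                         file.path(config$output_dir,
                                   "irt_thresholds.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 6)
    note("irt", nrow(irt$params), list(mode = irt$mode))
  }

  scores <- score_mhc(responses)
  splits <- NULL
  if (run("mhc")) {
    splits <- median_split(scores)
    results$mhc <- list(scores = scores, splits = splits)
    utils::write.csv(scores, file.path(config$output_dir, "mhc_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(splits$labels), row.names = FALSE,
                     file.path(config$output_dir, "mhc_splits.csv"))
    jsonlite::write_json(as.list(splits$medians),
                         file.path(config$output_dir, "mhc_medians.json"),
                         auto_unbox = TRUE)
    note("mhc", nrow(scores), list(medians = as.list(splits$medians)))
  }

  scr <- NULL
  if (run("screen")) {
    if (is.null(splits)) splits <- median_split(scores)
    scr <- screen_nutrients(nutrients, splits, alpha = config$alpha)
    results$screen <- scr
    utils::write.csv(scr$cells, file.path(config$output_dir, "screen.csv"),
                     row.names = FALSE)
    note("screen", nrow(scr$cells),
         list(selected = scr$selected, n_tests = scr$n_tests,
              caveat = sprintf(
                "%d unadjusted tests at alpha = %g", scr$n_tests,
                config$alpha)))
  }

  cut <- NULL
  if (run("cutoffs") && !is.null(scr)) {
    overrides <- config$cutoff_overrides
    if (is.character(overrides) && length(overrides) == 1) {
      ov <- utils::read.csv(overrides, stringsAsFactors = FALSE)
      overrides <- stats::setNames(ov$cutoff, ov$nutrient)
    }
    cut <- derive_cutoffs(scr, overrides = overrides)
    results$cutoffs <- cut
    utils::write.csv(cut, file.path(config$output_dir, "cutoffs.csv"),
                     row.names = FALSE)
    if (any(cut$empty))
      manifest$warnings <- c(manifest$warnings,
                             paste("empty feasible interval for:",
                                   paste(cut$nutrient[cut$empty],
                                         collapse = ", ")))
    note("cutoffs", nrow(cut))
  }

  if (run("stratify") && !is.null(cut)) {
    usable <- cut[!is.na(cut$cutoff), ]
    strat <- stratify_and_compare(nutrients, usable, scores,
                                  alpha = config$alpha)
    results$stratify <- strat
    utils::write.csv(strat$groups,
                     file.path(config$output_dir, "ncount_groups.csv"),
                     row.names = FALSE)
    utils::write.csv(strat$summary,
                     file.path(config$output_dir, "ncount_summary.csv"),
                     row.names = FALSE)
    note("stratify", nrow(strat$groups),
         list(group_sizes = as.list(table(strat$groups$group))))
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest", outputs)]
  manifest$checksums <- as.list(tools::md5sum(sort(outputs)))
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  attr(manifest, "results") <- results
  invisible(manifest)
}
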