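# Shared fixtures, generated in code.  The default cohort (the stated
# world: 887 records, 75 non-worker / 18 high-stress flags, 17 planted
# nutrients) is expensive enough to be worth memoising across tests.

.fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(.fixture_env$default)) {
    cohort <- generate_cohort(generator_config())
    flt <- filter_population(cohort$subjects)
    keep <- cohort$responses$subject_id %in% flt$included
    responses <- cohort$responses[keep, ]
    nutrients <- cohort$nutrients[cohort$nutrients$subject_id %in%
                                    flt$included, ]
    .fixture_env$default <- list(
      cohort = cohort, filter = flt, responses = responses,
      nutrients = nutrients, binary = recode_binary(responses),
      theta = cohort$theta[keep, ])
  }
  .fixture_env$default
}

# small all-items Likert matrix helper
likert_fixture <- function(values, n = 1) {
  m <- matrix(values, n, 29, byrow = length(values) == 29)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("Q%02d", 1:29))
  m
}

# correlated latent MHC matrix for generator module tests
mhc_latent_fixture <- function(n, rho = 0.5, seed = 1) {
  set.seed(seed)
  S <- matrix(rho, 4, 4); diag(S) <- 1
  matrix(rnorm(n * 4), n, 4) %*% chol(S)
}
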