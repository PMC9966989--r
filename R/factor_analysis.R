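# Factor structure of the 29 dichotomised items: sampling adequacy (KMO),
# factor-count criteria (scree eigenvalues, Horn's parallel analysis,
# Velicer's MAP), maximum-likelihood exploratory extraction with direct
# Oblimin rotation, loading-based item assignment, and a maximum-likelihood
# confirmatory fit with CFI/TLI/SRMR.
#
# By default all analyses run on Pearson correlations of the 0/1 recoded
# items (the recode-then-analyse order of the source procedure); a
# tetrachoric option is available for the correlation step.

as_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-8 &&
      max(abs(diag(x) - 1)) < 1e-8)
    return(list(R = x, n = NA_integer_))
  list(R = stats::cor(x), n = nrow(x))
}

#' Tetrachoric correlation matrix of binary items
#'
#' Pairwise tetrachoric correlations estimated by maximum likelihood over
#' the 2x2 tables (thresholds fixed at the marginal normal quantiles).
#' Offered as an alternative to Pearson correlations of the 0/1 items;
#' not the default anywhere.
#'
#' @param binary 0/1 matrix.
#' @return Correlation matrix.
#' @export
tetrachoric_cor <- function(binary) {
  binary <- as.matrix(binary)
  p <- ncol(binary)
  R <- diag(p)
  tau <- stats::qnorm(pmin(pmax(colMeans(binary), 1e-6), 1 - 1e-6))
  n <- nrow(binary)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    n11 <- sum(binary[, i] == 1 & binary[, j] == 1)
    n10 <- sum(binary[, i] == 1 & binary[, j] == 0)
    n01 <- sum(binary[, i] == 0 & binary[, j] == 1)
    n00 <- n - n11 - n10 - n01
    negll <- function(r) {
      r <- tanh(r)
      p11 <- pbivnorm_upper(tau[i], tau[j], r)
      p1 <- 1 - stats::pnorm(tau[i]); p2 <- 1 - stats::pnorm(tau[j])
      p10 <- pmax(p1 - p11, 1e-12); p01 <- pmax(p2 - p11, 1e-12)
      p00 <- pmax(1 - p1 - p2 + p11, 1e-12); p11 <- pmax(p11, 1e-12)
      -(n11 * log(p11) + n10 * log(p10) + n01 * log(p01) + n00 * log(p00))
    }
    opt <- stats::optimize(negll, c(-6, 6))
    R[i, j] <- R[j, i] <- tanh(opt$minimum)
  }
  dimnames(R) <- list(colnames(binary), colnames(binary))
  R
}

# Upper-tail bivariate normal probability P(X > a, Y > b; rho) by
# Gauss-Legendre quadrature over the conditional distribution.
pbivnorm_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return((1 - stats::pnorm(a)) * (1 - stats::pnorm(b)))
  gl <- gauss_legendre(32)
  lo <- a; hi <- max(a + 8, 8)
  x <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  w <- (hi - lo) / 2 * gl$weights
  integrand <- stats::dnorm(x) *
    (1 - stats::pnorm((b - rho * x) / sqrt(1 - rho^2)))
  sum(w * integrand)
}

gauss_legendre <- function(n) {
  # Golub-Welsch on the Jacobi matrix for Legendre polynomials on [-1, 1]
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of summed squared simple correlations to the sum
#' of squared simple plus squared anti-image partial correlations over all
#' off-diagonal pairs.
#'
#' @param x Correlation matrix, or a data matrix from which Pearson
#'   correlations are taken.
#' @return Overall KMO in `[0, 1]`.
#' @export
#' @examples
#' R <- matrix(0.5, 3, 3); diag(R) <- 1
#' kmo(R)
kmo <- function(x) {
  R <- as_correlation(x)$R
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("KMO error: correlation matrix is singular or near-singular (",
         conditionMessage(e), ")"))
  d <- 1 / sqrt(diag(Rinv))
  P <- -Rinv * outer(d, d)          # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

#' Factor-count criteria: scree eigenvalues, parallel analysis, MAP
#'
#' Horn's parallel analysis compares the eigenvalues of the observed
#' correlation matrix with a chosen percentile of eigenvalues from
#' independent standard-normal data of the same dimensions; the retained
#' count is the number of observed eigenvalues exceeding their simulated
#' counterpart.  Velicer's minimum-average-partial (MAP) count is the
#' number of principal components at which the average squared partial
#' correlation is minimised.
#'
#' @param x Binary (or any numeric) data matrix, subjects x items.
#' @param n_iter Number of random datasets for parallel analysis
#'   (default 100).
#' @param percentile Percentile of the simulated eigenvalue distribution
#'   (default 95).
#' @param seed Seed for the random datasets.
#' @return List with `eigenvalues`, `random_quantiles`, `parallel` (count),
#'   `map` (count), `map_profile`.
#' @export
count_factors <- function(x, n_iter = 100, percentile = 95, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("need at least two items")
  R <- stats::cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  rand <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  qs <- apply(rand, 1, stats::quantile, probs = percentile / 100)
  parallel <- {
    above <- ev > qs
    if (all(above)) p else if (!above[1]) 0L else which.min(above) - 1L
  }
  # Velicer's MAP
  e <- eigen(R, symmetric = TRUE)
  map_profile <- numeric(p - 1)
  off <- upper.tri(R)
  map0 <- mean(R[off]^2)
  for (m in seq_len(p - 1)) {
    Lm <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    C <- R - tcrossprod(Lm)
    d <- sqrt(pmax(diag(C), 1e-12))
    P <- C / outer(d, d)
    map_profile[m] <- mean(P[off]^2)
  }
  map <- if (map0 < min(map_profile)) 0L else which.min(map_profile)
  list(eigenvalues = ev, random_quantiles = qs,
       parallel = as.integer(parallel), map = as.integer(map),
       map_profile = map_profile)
}

# Quartimin/oblimin criterion value and gradient for loadings L.
vgQ_oblimin <- function(L, gam = 0) {
  p <- nrow(L); k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- if (gam == 0) L2 %*% N
       else (diag(p) - gam * matrix(1 / p, p, p)) %*% L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Gradient-projection oblique rotation (Jennrich 2002 / Bernaards-Jennrich).
gpf_oblq <- function(A, gam = 0, maxit = 1000, tol = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  L <- A %*% t(solve(Tmat))
  vg <- vgQ_oblimin(L, gam)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  al <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    repeat {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      vgt <- vgQ_oblimin(Lt, gam)
      if (vgt$f < f - 0.5 * s^2 * al || al < 1e-12) break
      al <- al / 2
    }
    Tmat <- Tt; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(loadings = L, phi = crossprod(Tmat), Tmat = Tmat, f = f,
       iterations = iter, converged = converged)
}

#' Maximum-likelihood exploratory factor analysis with Oblimin rotation
#'
#' Extracts `k` factors by maximum likelihood and rotates them obliquely by
#' the direct Oblimin criterion (gradient-projection algorithm; `gamma = 0`
#' is direct quartimin, the default).  Factor columns are ordered by
#' explained common variance and signed so that each column's
#' largest-magnitude loading is positive.
#'
#' @param x Data matrix (subjects x items) or a correlation matrix.
#' @param k Number of factors.
#' @param gam Oblimin gamma (default 0).
#' @param n_obs Number of observations when `x` is a correlation matrix.
#' @return Object of class `factor_solution`: `pattern` (p x k), `phi`
#'   (k x k factor correlations), `communalities`, `uniquenesses`,
#'   `method`, `heywood` (logical), `rotation` convergence info.
#' @export
efa <- function(x, k, gam = 0, n_obs = NULL) {
  cr <- as_correlation(x)
  R <- cr$R
  p <- ncol(R)
  if (k < 1 || k >= p) stop("k must be in [1, items)")
  n_obs <- if (!is.null(n_obs)) n_obs else if (!is.na(cr$n)) cr$n else 1000
  fa <- stats::factanal(covmat = R, factors = k, rotation = "none",
                        n.obs = n_obs)
  A <- matrix(fa$loadings, p, k)
  rownames(A) <- colnames(R)
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-8)
  if (heywood)
    warning("Heywood case: communality at bound for ",
            paste(colnames(R)[fa$uniquenesses <= 0.005 + 1e-8],
                  collapse = ", "), "; uniqueness bounded, estimation continued")
  if (k == 1) {
    rot <- list(loadings = A, phi = matrix(1, 1, 1), converged = TRUE,
                iterations = 0L, f = 0)
  } else {
    rot <- gpf_oblq(A, gam = gam)
  }
  P <- rot$loadings
  phi <- rot$phi
  # canonical column order: explained common variance (structure-weighted)
  ssl <- colSums((P %*% phi) * P)
  ord <- order(ssl, decreasing = TRUE)
  P <- P[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  sgn <- vapply(seq_len(k), function(j) {
    v <- P[, j]; if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  P <- P %*% diag(sgn, k)
  phi <- diag(sgn, k) %*% phi %*% diag(sgn, k)
  colnames(P) <- colnames(phi) <- rownames(phi) <- paste0("ML", seq_len(k))
  comm <- rowSums((P %*% phi) * P)
  structure(list(pattern = P, phi = phi, communalities = comm,
                 uniquenesses = fa$uniquenesses, method = "ml+oblimin",
                 gam = gam, heywood = heywood,
                 rotation = rot[c("converged", "iterations", "f")]),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, cutoff = 0.29, ...) {
  cat("Maximum-likelihood factor solution (direct Oblimin, gamma =",
      x$gam, ")\n")
  P <- round(x$pattern, 2)
  P[abs(P) < cutoff] <- NA
  print(P, na.print = "")
  cat("\nFactor correlations:\n")
  print(round(x$phi, 2))
  if (x$heywood) cat("\nWarning: Heywood case encountered.\n")
  invisible(x)
}

#' Assign items to factors by maximal loading
#'
#' Each item is assigned to the factor on which it has its
#' largest-magnitude pattern loading, provided that loading reaches
#' `threshold`; items below threshold on every factor are left unassigned.
#' The default threshold 0.29 retains the smallest loading printed in the
#' reference pattern solution.
#'
#' @param solution A `factor_solution`, or a bare pattern matrix.
#' @param threshold Loading cut in (0, 1).
#' @return List with `assignment` (named character vector item -> factor,
#'   `NA` for unassigned) and `unassigned` (character vector).
#' @export
assign_items <- function(solution, threshold = 0.29) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  P <- if (inherits(solution, "factor_solution")) solution$pattern
       else as.matrix(solution)
  fac <- colnames(P)
  if (is.null(fac)) fac <- paste0("ML", seq_len(ncol(P)))
  assignment <- apply(P, 1, function(v) {
    j <- which.max(abs(v))
    if (abs(v[j]) >= threshold) fac[j] else NA_character_
  })
  list(assignment = assignment,
       unassigned = names(assignment)[is.na(assignment)])
}

# Phi parameterisation for the CFA: unit-diagonal PSD matrix from
# unconstrained row parameters (normalised Cholesky rows).
phi_from_pars <- function(z, k) {
  Lc <- diag(k)
  if (k > 1) {
    idx <- 1
    for (i in 2:k) {
      row <- c(z[idx:(idx + i - 2)], 1)
      idx <- idx + i - 1
      Lc[i, seq_len(i)] <- row / sqrt(sum(row^2))
    }
  }
  tcrossprod(Lc)
}

#' Confirmatory factor analysis by maximum likelihood
#'
#' Fits the congeneric model implied by an item-to-factor map (each item
#' loads on exactly one factor; factors freely correlated; uniquenesses
#' free) by minimising the ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` over loadings,
#' uniquenesses and factor correlations.  CFI and TLI are computed against
#' the independence baseline; SRMR is the root mean squared residual of
#' the (standardized) solution over the lower triangle including the
#' diagonal.
#'
#' @param x Data matrix or correlation matrix.
#' @param model Named character vector mapping item -> factor (as from
#'   [assign_items()]), or a list of item sets.
#' @param n_obs Observations when `x` is a correlation matrix.
#' @param max_iter Optimiser iteration cap.
#' @return Object of class `cfa_fit`: `cfi`, `tli`, `srmr`, `chisq`, `df`,
#'   `baseline_chisq`, `baseline_df`, `loadings` (standardized), `phi`,
#'   `uniquenesses`, `converged`.
#' @export
cfa_fit <- function(x, model, n_obs = NULL, max_iter = 2000) {
  cr <- as_correlation(x)
  S <- cr$R
  n_obs <- if (!is.null(n_obs)) n_obs else if (!is.na(cr$n)) cr$n else
    stop("n_obs required when x is a correlation matrix")
  if (is.list(model)) {
    model <- stats::setNames(rep(names(model), lengths(model)),
                             unlist(model))
  }
  model <- model[!is.na(model)]
  items <- names(model)
  if (!all(items %in% colnames(S)))
    stop("model names items absent from the data: ",
         paste(setdiff(items, colnames(S)), collapse = ", "))
  S <- S[items, items]
  p <- length(items)
  fac <- unique(model)
  k <- length(fac)
  if (any(table(model) < 2)) stop("every factor needs >= 2 items")
  fidx <- match(model, fac)
  # start values: loading 0.6, uniqueness 0.64, phi ~ 0.3
  start <- c(rep(0.6, p), rep(log(0.64), p),
             if (k > 1) rep(0.45, k * (k - 1) / 2) else numeric(0))
  ldetS <- determinant(S, logarithm = TRUE)$modulus
  objective <- function(par) {
    lam <- par[seq_len(p)]
    psi <- exp(par[p + seq_len(p)])
    z <- if (k > 1) par[2 * p + seq_len(k * (k - 1) / 2)] else numeric(0)
    phi <- phi_from_pars(z, k)
    L <- matrix(0, p, k)
    L[cbind(seq_len(p), fidx)] <- lam
    Sigma <- L %*% phi %*% t(L) + diag(psi, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    as.numeric(ldet + tr - ldetS - p)
  }
  opt <- stats::nlminb(start, objective,
                       control = list(iter.max = max_iter,
                                      eval.max = 4 * max_iter))
  if (opt$convergence != 0 && opt$objective > 1e9)
    stop("CFA did not converge: ", opt$message)
  par <- opt$par
  lam <- par[seq_len(p)]
  psi <- exp(par[p + seq_len(p)])
  phi <- phi_from_pars(if (k > 1) par[2 * p + seq_len(k * (k - 1) / 2)]
                       else numeric(0), k)
  # sign convention: majority-positive loadings per factor
  for (j in seq_len(k)) {
    sel <- fidx == j
    if (sum(lam[sel]) < 0) {
      lam[sel] <- -lam[sel]
      if (k > 1) { phi[j, -j] <- -phi[j, -j]; phi[-j, j] <- -phi[-j, j] }
    }
  }
  L <- matrix(0, p, k, dimnames = list(items, fac))
  L[cbind(seq_len(p), fidx)] <- lam
  Sigma <- L %*% phi %*% t(L) + diag(psi, p)
  fmin <- opt$objective
  df <- p * (p + 1) / 2 - (p + p + k * (k - 1) / 2)
  chisq <- max((n_obs - 1) * fmin, 0)
  base_f <- as.numeric(-ldetS)   # independence model on a correlation matrix
  base_chisq <- max((n_obs - 1) * base_f, 0)
  base_df <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(base_chisq - base_df, chisq - df, 1e-12)
  tli <- if (df > 0)
    (base_chisq / base_df - chisq / df) / (base_chisq / base_df - 1)
  else 1
  resid <- S - Sigma
  lowtri <- lower.tri(resid, diag = TRUE)
  srmr <- sqrt(mean(resid[lowtri]^2))
  dimnames(phi) <- list(fac, fac)
  structure(list(cfi = cfi, tli = tli, srmr = srmr,
                 chisq = chisq, df = df,
                 baseline_chisq = base_chisq, baseline_df = base_df,
                 loadings = L, phi = phi,
                 uniquenesses = stats::setNames(psi, items),
                 fmin = fmin, n_obs = n_obs,
                 converged = opt$convergence == 0),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(
    "CFA (ML): chisq = %.2f on %d df; CFI = %.3f, TLI = %.3f, SRMR = %.3f\n",
    x$chisq, x$df, x$cfi, x$tli, x$srmr))
  invisible(x)
}
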