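# Two-parameter logistic IRT: Bock-Aitkin marginal maximum likelihood EM
# under a standard-normal latent trait with Gauss-Hermite quadrature,
# factor-level averaged response curves, and 0.5-probability thresholds.

#' Gauss-Hermite quadrature adapted to the standard normal
#'
#' Nodes and weights such that `sum(w * f(x))` approximates
#' `E[f(Z)], Z ~ N(0, 1)` (Golub-Welsch on the Hermite Jacobi matrix).
#'
#' @param n Number of quadrature points.
#' @return List with `nodes` and `weights` (weights sum to 1).
#' @export
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  beta <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  # physicists' Hermite nodes x; transform to z = sqrt(2) x, w / sqrt(pi)
  list(nodes = sqrt(2) * e$values[idx],
       weights = e$vectors[1, idx]^2)
}

#' 2PL item characteristic curve
#'
#' `P(endorse | theta) = 1 / (1 + exp(-a (theta - b)))`.
#'
#' @param theta Latent trait value(s).
#' @param a Discrimination.
#' @param b Difficulty (trait value at which P = 0.5).
#' @return Endorsement probability.
#' @export
#' @examples
#' icc(0, a = 1.7, b = 0)  # 0.5 by definition of difficulty
icc <- function(theta, a, b) {
  stats::plogis(a * (theta - b))
}

#' Fit a 2PL model by marginal maximum likelihood (Bock-Aitkin EM)
#'
#' The latent trait is identified as standard normal; the marginal
#' likelihood is integrated by Gauss-Hermite quadrature.  The E-step
#' computes expected per-node response counts from the posterior over
#' nodes; the M-step solves one weighted logistic regression per item to
#' convergence, so the marginal log-likelihood is non-decreasing across EM
#' iterations.  Items with zero observed variance are excluded with a
#' warning.
#'
#' @param binary 0/1 response matrix, subjects x items.
#' @param quadrature Number of quadrature points (default 21).
#' @param tol EM convergence tolerance on the maximum parameter change
#'   (default 1e-4).
#' @param max_iter Maximum EM iterations (default 500).
#' @param a_max Bound on the discrimination magnitude (default 6).  With
#'   few, highly discriminating items the ML slope estimate can drift
#'   towards infinity on an essentially flat likelihood; the bound keeps
#'   such items estimable and is reported when hit.
#' @return Object of class `irt_2pl`: `params` (data frame `item`, `a`,
#'   `b`), `loglik`, `loglik_trace`, `iterations`, `converged`,
#'   `excluded` (zero-variance items), `quadrature`.
#' @export
fit_2pl <- function(binary, quadrature = 21, tol = 1e-4, max_iter = 500,
                    a_max = 6) {
  Y <- as.matrix(binary)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("item", seq_len(ncol(Y)))
  if (any(is.na(Y)) || !all(Y %in% c(0, 1)))
    stop("binary matrix must contain only 0/1 with no missing cells")
  v <- apply(Y, 2, stats::var)
  excluded <- colnames(Y)[v == 0]
  if (length(excluded)) {
    warning("excluding zero-variance item(s): ",
            paste(excluded, collapse = ", "))
    Y <- Y[, v > 0, drop = FALSE]
  }
  n <- nrow(Y); p <- ncol(Y)
  if (p == 0) stop("no items left to fit")
  if (n < p) stop("need at least as many subjects as items")
  gh <- gauss_hermite_normal(quadrature)
  xq <- gh$nodes; logw <- log(gh$weights)
  # start: a = 1, b from endorsement rate
  a <- rep(1, p)
  b <- -stats::qlogis(pmin(pmax(colMeans(Y), 0.01), 0.99))
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: posterior over quadrature nodes
    P <- stats::plogis(outer(xq, b, "-") * rep(a, each = quadrature))
    P <- t(P)                                  # p x q
    logP <- log(pmax(P, 1e-300)); log1P <- log(pmax(1 - P, 1e-300))
    ll_iq <- Y %*% logP + (1 - Y) %*% log1P    # n x q
    ll_iq <- sweep(ll_iq, 2, logw, "+")
    mx <- apply(ll_iq, 1, max)
    W <- exp(ll_iq - mx)
    rs <- rowSums(W)
    loglik <- sum(mx + log(rs))
    W <- W / rs
    nq <- colSums(W)                           # expected count per node
    rjq <- crossprod(Y, W)                     # p x q expected endorsements
    # M-step: per-item weighted logistic regression on the nodes
    a_new <- a; b_new <- b
    for (j in seq_len(p)) {
      alpha <- a[j]; beta0 <- -a[j] * b[j]
      for (inner in 1:25) {
        eta <- alpha * xq + beta0
        pj <- stats::plogis(eta)
        wj <- nq * pj * (1 - pj)
        g <- c(sum((rjq[j, ] - nq * pj) * xq), sum(rjq[j, ] - nq * pj))
        H <- matrix(c(sum(wj * xq^2), sum(wj * xq),
                      sum(wj * xq), sum(wj)), 2, 2)
        step <- tryCatch(solve(H + diag(1e-10, 2), g),
                         error = function(e) c(0, 0))
        # damp extreme steps for stability
        step <- pmin(pmax(step, -2), 2)
        alpha <- alpha + step[1]; beta0 <- beta0 + step[2]
        if (abs(alpha) > a_max) alpha <- sign(alpha) * a_max
        if (max(abs(step)) < 1e-9) break
      }
      a_new[j] <- alpha; b_new[j] <- -beta0 / alpha
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    loglik_trace <- c(loglik_trace, loglik)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("2PL EM did not converge after ", max_iter,
         " iterations; last max parameter change = ",
         signif(delta, 3), "; log-likelihood trace tail: ",
         paste(signif(utils::tail(loglik_trace, 3), 8), collapse = ", "))
  # sign convention: higher theta = unfavourable pole more likely
  if (sum(a) < 0) { a <- -a; b <- -b }
  structure(list(params = data.frame(item = colnames(Y), a = a, b = b,
                                     stringsAsFactors = FALSE),
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace,
                 iterations = length(loglik_trace),
                 converged = converged, excluded = excluded,
                 at_bound = colnames(Y)[abs(a) >= a_max - 1e-6],
                 quadrature = quadrature),
            class = "irt_2pl")
}

#' @export
print.irt_2pl <- function(x, ...) {
  cat(sprintf("2PL fit: %d items, logLik %.2f after %d EM iterations\n",
              nrow(x$params), x$loglik, x$iterations))
  print(x$params, digits = 3)
  invisible(x)
}

#' Factor-level averaged response curve
#'
#' The pointwise mean of the member items' characteristic curves over a
#' trait grid.  Averaging over items with dispersed difficulties flattens
#' the curve, which is how a broadly-appearing complaint (e.g. somatic
#' symptoms) manifests.
#'
#' @param items Character vector of item codes (or indices) in `params`.
#' @param params An `irt_2pl` fit or its `params` data frame.
#' @param grid Trait grid (default `seq(-4, 4, by = 0.01)`).
#' @return Object of class `response_curve`: data frame `theta`, `p`, with
#'   the member parameters kept as attributes for analytic refinement.
#' @export
factor_curve <- function(items, params, grid = seq(-4, 4, by = 0.01)) {
  if (inherits(params, "irt_2pl")) params <- params$params
  if (length(items) == 0) stop("empty item set")
  sel <- params[match(items, params$item), ]
  if (anyNA(sel$a)) stop("unknown item(s): ",
                         paste(items[is.na(sel$a)], collapse = ", "))
  pvals <- rowMeans(vapply(seq_len(nrow(sel)),
                           function(j) icc(grid, sel$a[j], sel$b[j]),
                           numeric(length(grid))))
  structure(data.frame(theta = grid, p = pvals),
            class = c("response_curve", "data.frame"),
            a = sel$a, b = sel$b, items = sel$item)
}

#' Trait threshold of a response curve
#'
#' The trait value at which the (monotone) curve crosses endorsement
#' probability 0.5: located by linear interpolation on the grid and
#' refined by bisection on the analytic averaged curve when the member
#' parameters are available.
#'
#' @param curve A `response_curve` (or data frame `theta`, `p`).
#' @return The crossing trait value.
#' @export
threshold <- function(curve) {
  th <- curve$theta; pv <- curve$p
  above <- pv >= 0.5
  if (all(above) || all(!above))
    stop("curve does not cross 0.5 on the grid; extend the grid")
  i <- which(above)[1]
  if (i == 1) return(th[1])
  x0 <- th[i - 1]; x1 <- th[i]
  a <- attr(curve, "a"); b <- attr(curve, "b")
  if (is.null(a)) {  # grid-only linear interpolation
    return(x0 + (0.5 - pv[i - 1]) / (pv[i] - pv[i - 1]) * (x1 - x0))
  }
  f <- function(t) mean(icc(t, a, b)) - 0.5
  lo <- x0; hi <- x1
  # widen bracket defensively (grid p may differ from analytic p)
  while (f(lo) > 0) lo <- lo - 0.5
  while (f(hi) < 0) hi <- hi + 0.5
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit per-factor 2PL models and extract thresholds
#'
#' Convenience wrapper: fits each factor's items jointly against one
#' latent trait (the default mode; a joint all-items fit is available via
#' `joint = TRUE`), builds the averaged response curve per factor, and
#' returns the 0.5-probability thresholds in trait units.
#'
#' @param binary 0/1 matrix of recoded responses.
#' @param factors Named list of item sets (default [mhc_factors()]).
#' @param joint Fit all items against a single trait instead (default
#'   FALSE).
#' @param grid Trait grid for the curves.
#' @param ... Passed to [fit_2pl()].
#' @return List with `fits` (per factor, or `$joint`), `params` (combined
#'   data frame with a `factor` column), `curves` (named list of
#'   `response_curve`), `thresholds` (named numeric).
#' @export
irt_thresholds <- function(binary, factors = mhc_factors(), joint = FALSE,
                           grid = seq(-6, 6, by = 0.01), ...) {
  binary <- as.matrix(binary)
  if (joint) {
    fit <- fit_2pl(binary, ...)
    fits <- list(joint = fit)
    params <- do.call(rbind, lapply(names(factors), function(f) {
      pp <- fit$params[fit$params$item %in% factors[[f]], ]
      if (nrow(pp)) pp$factor <- f
      pp
    }))
  } else {
    fits <- lapply(factors, function(it) {
      fit_2pl(binary[, it, drop = FALSE], ...)
    })
    params <- do.call(rbind, lapply(names(factors), function(f) {
      pp <- fits[[f]]$params
      if (nrow(pp)) pp$factor <- f
      pp
    }))
  }
  rownames(params) <- NULL
  curves <- lapply(names(factors), function(f) {
    pp <- params[params$factor == f, ]
    factor_curve(pp$item, pp, grid = grid)
  })
  names(curves) <- names(factors)
  thresholds <- vapply(curves, threshold, numeric(1))
  list(fits = fits, params = params, curves = curves,
       thresholds = thresholds, mode = if (joint) "joint" else "per-factor")
}
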