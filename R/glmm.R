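#' Specify a binomial random-intercept mixed model
#'
#' Bundles one SNP's binary genotype vector, a fixed-effect design matrix and
#' a grouping factor (country) into a validated model specification. Constant
#' non-intercept columns are dropped, as are columns aliased with earlier
#' ones, so the retained design has full column rank.
#'
#' @param y binary response vector (0/1), one entry per individual.
#' @param X numeric design matrix with an intercept column; rows align with
#'   `y`. A column named `"(Intercept)"` is added when absent.
#' @param group factor or character vector of group labels (one per row).
#' @return an object of class `glmm_spec` with elements `y`, `X`, `group`
#'   (factor), `dropped` (names of removed columns), and a group-sorted
#'   internal layout used by the fitting engine.
#' @export
glmm_spec <- function(y, X, group) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1 with no missing values")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- rep("", ncol(X))
  colnames(X)[colnames(X) == "" | is.na(colnames(X))] <-
    paste0("x", which(colnames(X) == "" | is.na(colnames(X))))
  if (!"(Intercept)" %in% colnames(X)) {
    ones <- which(apply(X, 2, function(v) all(v == 1)))
    if (length(ones)) colnames(X)[ones[1]] <- "(Intercept)"
    else X <- cbind(`(Intercept)` = 1, X)
  }
  if (nrow(X) != length(y)) stop("design and response dimensions differ")
  group <- factor(group)
  if (length(group) != length(y)) stop("grouping and response dimensions differ")
  if (any(table(group) == 0L)) stop("every group must be non-empty")

  dropped <- character(0)
  keep <- colnames(X) == "(Intercept)" | apply(X, 2, function(v) sd(v) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    alias <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    dropped <- c(dropped, alias)
    X <- X[, setdiff(colnames(X), alias), drop = FALSE]
  }

  ord <- order(as.integer(group))
  gi <- as.integer(group)[ord]
  bounds <- c(0L, cumsum(tabulate(gi, nbins = nlevels(group))))
  structure(list(
    y = y, X = X, group = group, dropped = dropped,
    ord = ord, gstart = bounds[-length(bounds)], gend = bounds[-1L]
  ), class = "glmm_spec")
}

#' Fit the binomial mixed model by Laplace-approximated maximum likelihood
#'
#' Maximises the Laplace approximation to the marginal likelihood of
#' `logit P(y=1) = X beta + u_g`, `u_g ~ N(0, sigma^2)`. The inner loop is a
#' penalised iteratively-reweighted least-squares solve for `(beta, u)`; the
#' outer loop is a derivative-free search over `log sigma` (profile method),
#' optionally polished by a joint bound-constrained quadratic-approximation
#' (BOBYQA) step over `(beta, log sigma)`. The `sigma = 0` boundary is always
#' evaluated (it is the ordinary logistic MLE) and returned when it attains
#' the larger objective. Non-convergence (including separation, detected as
#' divergence of the coefficients) is reported, never silently accepted.
#'
#' @param spec a [glmm_spec()].
#' @param max_iter iteration cap passed to the BOBYQA polish.
#' @param tol convergence tolerance on the objective.
#' @param method `"profile"` (default) or `"bobyqa"` (profile + joint polish).
#' @param restarts number of perturbed restarts before declaring failure.
#' @param beta_init optional starting coefficients.
#' @return an object of class `glmm_fit`: `beta`, `sigma`, `loglik`,
#'   `converged`, `n_iter`, `u` (conditional modes, named by group),
#'   `eta` (linear predictor, original row order), `dispersion`, `diagnostic`.
#' @export
fit_glmm <- function(spec, max_iter = 100000L, tol = 1e-8,
                     method = c("profile", "bobyqa"), restarts = 3L,
                     beta_init = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  method <- match.arg(method)
  ys <- spec$y[spec$ord]
  Xs <- spec$X[spec$ord, , drop = FALSE]
  p <- ncol(Xs)
  b0 <- if (is.null(beta_init)) rep(0, p) else as.numeric(beta_init)
  if (length(b0) != p) b0 <- rep(0, p)

  fit <- NULL
  for (r in 0:restarts) {
    # deterministic perturbations keep refits byte-reproducible
    start <- if (r == 0) b0 else b0 + 0.25 * r * sin(seq_len(p) * (2.7 * r + 1))
    cand <- .cpp_fit_profile(ys, Xs, spec$gstart, spec$gend, start,
                             log_sigma_lo = -4.5, log_sigma_hi = 1.8,
                             tol = 1e-5)
    if (cand$converged) { fit <- cand; break }
    if (is.null(fit)) fit <- cand
  }
  diagnostic <- if (fit$converged) NA_character_ else
    "inner PIRLS diverged or stalled (possible separation / degenerate site)"

  if (method == "bobyqa" && fit$converged) {
    nll <- function(par) {
      s <- exp(par[p + 1])
      -.cpp_laplace_loglik(ys, Xs, spec$gstart, spec$gend, par[seq_len(p)], s)$loglik
    }
    start <- c(fit$beta, log(max(fit$sigma, 1e-3)))
    bb <- minqa::bobyqa(start, nll,
                        lower = c(rep(-BETA_BOUND, p), -8),
                        upper = c(rep(BETA_BOUND, p), 3),
                        control = list(maxfun = max_iter, rhoend = tol))
    if (-bb$fval > fit$loglik + tol) {
      lap <- .cpp_laplace_loglik(ys, Xs, spec$gstart, spec$gend,
                                 bb$par[seq_len(p)], exp(bb$par[p + 1]))
      fit$beta <- bb$par[seq_len(p)]
      fit$sigma <- exp(bb$par[p + 1])
      fit$loglik <- lap$loglik
      fit$u <- lap$u
      eta_s <- as.numeric(Xs %*% fit$beta) + lap$u[as.integer(spec$group)[spec$ord]]
      fit$eta <- eta_s
    }
    # boundary re-check after polish
    if (fit$loglik_sigma0 >= fit$loglik - tol) {
      z <- .cpp_fit_profile(ys, Xs, spec$gstart, spec$gend, fit$beta,
                            -4.5, 1.8, 1e-5)
      if (isTRUE(z$converged) && isTRUE(z$sigma == 0)) fit <- z
    }
  }

  eta <- numeric(length(ys))
  eta[spec$ord] <- fit$eta
  u <- as.numeric(fit$u)
  names(u) <- levels(spec$group)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(spec$X)
  out <- structure(list(
    beta = beta, sigma = fit$sigma, loglik = fit$loglik,
    converged = fit$converged, n_iter = fit$n_iter, u = u, eta = eta,
    p_fixed = p, diagnostic = diagnostic
  ), class = "glmm_fit")
  out$dispersion <- if (fit$converged) dispersion_ratio(out, spec) else NA_real_
  out
}

BETA_BOUND <- 40

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial random-intercept GLMM (Laplace)\n")
  cat("  logLik:", format(x$loglik), " sigma:", format(x$sigma),
      " converged:", x$converged, "\n")
  print(x$beta)
  invisible(x)
}

#' Laplace marginal log-likelihood at given parameters
#'
#' Evaluates the Laplace-approximated marginal log-likelihood of a
#' specification at arbitrary `(beta, sigma)`, with the conditional modes
#' recomputed by per-group Newton iteration.
#'
#' @inheritParams fit_glmm
#' @param beta fixed-effect coefficients (length = columns of the design).
#' @param sigma random-intercept standard deviation, `>= 0`.
#' @return scalar log-likelihood.
#' @export
loglik_laplace <- function(spec, beta, sigma) {
  stopifnot(inherits(spec, "glmm_spec"), sigma >= 0)
  ys <- spec$y[spec$ord]
  Xs <- spec$X[spec$ord, , drop = FALSE]
  .cpp_laplace_loglik(ys, Xs, spec$gstart, spec$gend, as.numeric(beta), sigma)$loglik
}

#' Adaptive Gauss-Hermite marginal log-likelihood (oracle)
#'
#' Exact-to-quadrature evaluation of the marginal log-likelihood by adaptive
#' Gauss-Hermite integration over each group's random intercept, recentred at
#' the conditional mode and rescaled by the local curvature. Intended as an
#' independent check of the Laplace objective; not used for fitting.
#'
#' @inheritParams loglik_laplace
#' @param n_nodes number of quadrature nodes (`>= 5`).
#' @return scalar log-likelihood.
#' @export
loglik_quadrature <- function(spec, beta, sigma, n_nodes = 30L) {
  stopifnot(inherits(spec, "glmm_spec"), n_nodes >= 5)
  if (sigma < 0) stop("sigma must be non-negative")
  ys <- spec$y[spec$ord]
  Xs <- spec$X[spec$ord, , drop = FALSE]
  xb <- as.numeric(Xs %*% as.numeric(beta))
  if (sigma == 0) {
    return(sum(ys * xb - log1p(exp(xb))))
  }
  lap <- .cpp_laplace_loglik(ys, Xs, spec$gstart, spec$gend, as.numeric(beta), sigma)
  gh <- pracma::gaussHermite(n_nodes)
  G <- length(spec$gstart)
  total <- 0
  for (g in seq_len(G)) {
    idx <- (spec$gstart[g] + 1L):spec$gend[g]
    ustar <- lap$u[g]
    H <- lap$Sg[g] + 1 / sigma^2           # negative Hessian at the mode
    s <- 1 / sqrt(H)
    uk <- ustar + sqrt(2) * s * gh$x
    gk <- vapply(uk, function(u) {
      eta <- xb[idx] + u
      sum(ys[idx] * eta - log1p(exp(eta))) -
        u^2 / (2 * sigma^2) - 0.5 * log(2 * pi * sigma^2)
    }, numeric(1))
    lg <- log(gh$w) + gh$x^2 + gk
    m <- max(lg)
    total <- total + log(sqrt(2) * s) + m + log(sum(exp(lg - m)))
  }
  total
}

#' Pearson dispersion ratio of a fitted model
#'
#' Sum of squared Pearson residuals, with fitted probabilities evaluated at
#' the conditional modes, divided by `n - p_fixed`. Ratios far below 1 signal
#' underdispersion (typically very rare alleles); the scan removes SNPs whose
#' null-model ratio falls below a threshold (default 0.8).
#'
#' @param fit a [fit_glmm()] result.
#' @param spec the matching [glmm_spec()].
#' @return scalar dispersion ratio.
#' @export
dispersion_ratio <- function(fit, spec) {
  stopifnot(inherits(fit, "glmm_fit"), inherits(spec, "glmm_spec"))
  p <- plogis(fit$eta)
  if (any(p < 1e-12 | p > 1 - 1e-12)) {
    warning("fitted probabilities at 0/1; Pearson residuals capped")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  sum((spec$y - p)^2 / (p * (1 - p))) / (length(spec$y) - fit$p_fixed)
}

#' Likelihood-ratio test of nested mixed models
#'
#' `2 * (loglik_alt - loglik_null)`, clamped at zero, referred to an
#' upper-tail chi-square with `df` degrees of freedom. If the alternative's
#' log-likelihood falls below the null's by more than a numerical tolerance
#' (a sign of misoptimisation), a warning is issued; callers refit with
#' restarts before reaching this point.
#'
#' @param null_fit,alt_fit converged [fit_glmm()] results on identical
#'   observations, alternative nesting the null.
#' @param df degrees of freedom = number of fixed effects added.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df) {
  stopifnot(inherits(null_fit, "glmm_fit"), inherits(alt_fit, "glmm_fit"), df >= 1)
  delta <- alt_fit$loglik - null_fit$loglik
  if (delta < -1e-6) {
    warning(sprintf(
      "alternative log-likelihood below null by %.3g despite nesting; check convergence",
      -delta))
  }
  stat <- max(0, 2 * delta)
  list(statistic = stat, p_value = pchisq(stat, df = df, lower.tail = FALSE), df = df)
}
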