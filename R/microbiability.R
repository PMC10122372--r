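# Microbial relationship matrix and REML estimation of "microbiability":
# the fraction of host phenotypic variance explained by microbial
# composition, the analogue of genomic heritability with taxa in place of
# markers.
#
# Model: y = X beta + m + e,  m ~ N(0, sigma2_m * M),  e ~ N(0, sigma2_e * I)
# with M built from centered, variance-standardized taxon abundances,
# M = Z Z' / N. The restricted likelihood is profiled down to one dimension
# (lambda = sigma2_m / sigma2_e) after a single eigendecomposition of M.

#' Build the microbial relationship matrix
#'
#' M_ij = (1/N) * sum_a (A_ia - Abar_a)(A_ja - Abar_a) / sigma2_a, where
#' sigma2_a is the population (divide-by-n) variance of taxon a. With this
#' standardization every column of Z has mean 0 and variance 1, so
#' trace(M) = n, the mean diagonal is 1, and rows/columns sum to 0.
#' Zero-variance taxa carry no relational information and are excluded from
#' N (with a warning).
#'
#' @param table An `abundance_table` or samples x taxa matrix of relative
#'   abundances.
#' @return An object of class `relationship_matrix` with elements `M`
#'   (n x n symmetric matrix), `n_taxa`, `taxon_means`, `taxon_vars`,
#'   `sample_ids`.
#' @export
build_relationship_matrix <- function(table) {
  A <- as_abundance_matrix(table)
  if (nrow(A) < 2L) stop("need at least 2 samples")
  v <- col_pop_var(A)
  keep <- v > 0
  if (!any(keep)) stop("no taxon with nonzero variance across samples")
  if (any(!keep))
    warning(sum(!keep), " zero-variance taxa excluded from the relationship matrix")
  A <- A[, keep, drop = FALSE]
  v <- v[keep]
  mu <- colMeans(A)
  Z <- sweep(sweep(A, 2L, mu, "-"), 2L, sqrt(v), "/")
  N <- ncol(Z)
  M <- tcrossprod(Z) / N
  M <- (M + t(M)) / 2  # enforce exact symmetry against round-off
  structure(list(M = M, n_taxa = N, taxon_means = mu, taxon_vars = v,
                 sample_ids = rownames(A)),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d samples, built from %d taxa (trace = %.4f)\n",
              nrow(x$M), x$n_taxa, sum(diag(x$M))))
  invisible(x)
}

as_M_matrix <- function(M) {
  if (inherits(M, "relationship_matrix")) M$M
  else if (is.matrix(M)) M
  else stop("expected a relationship_matrix or a square matrix")
}

# Profile REML log-likelihood at ratio lambda = sigma2_m/sigma2_e, on data
# rotated by the eigenvectors of M. d: eigenvalues, yt/Xt: rotated y and X.
# Returns the restricted log-likelihood with sigma2_e profiled out, plus the
# profiled sigma2_e and GLS fixed effects.
reml_profile_point <- function(log_lambda, d, yt, Xt) {
  lambda <- exp(log_lambda)
  n <- length(yt)
  p <- ncol(Xt)
  v <- lambda * d + 1
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 * w)
  sigma2_e <- rss / (n - p)
  if (!is.finite(sigma2_e) || sigma2_e <= 0) {
    return(list(loglik = Inf, sigma2_e = max(sigma2_e, 0), beta = drop(beta),
                degenerate = TRUE))
  }
  ll <- -0.5 * ((n - p) * log(sigma2_e) + sum(log(v)) +
                  2 * sum(log(diag(ch))) + (n - p) * (1 + log(2 * pi)))
  list(loglik = ll, sigma2_e = sigma2_e, beta = drop(beta), degenerate = FALSE)
}

#' Fit the microbiability linear mixed model by REML
#'
#' Maximizes the restricted likelihood of `y` under
#' `V = sigma2_m * M + sigma2_e * I` with fixed effects `X = [1 | covariates]`.
#' M is eigendecomposed once, `y` and `X` are rotated into its eigenbasis,
#' and the restricted likelihood is profiled over the variance ratio
#' `lambda = sigma2_m / sigma2_e` on a log scale: a coarse bracketing grid
#' followed by golden-section/parabolic refinement (`stats::optimize`), with
#' closed-form `sigma2_e` at each lambda. Boundary optima are flagged.
#'
#' @param y Numeric phenotype vector.
#' @param covariates Numeric matrix (or data frame) of covariates, without
#'   an intercept column; may be `NULL` for an intercept-only model.
#' @param M A `relationship_matrix` or n x n kernel matrix.
#' @param bounds Search interval for lambda (default `c(1e-6, 1e6)`).
#' @param tol Convergence tolerance on log(lambda) (default `1e-8`).
#' @param grid_n Number of coarse bracketing grid points (default 401).
#' @return An object of class `variance_components`: `sigma2_m`, `sigma2_e`,
#'   `lambda`, `beta` (named fixed effects), `loglik` (restricted
#'   log-likelihood at the optimum), `microbiability`
#'   (= sigma2_m / (sigma2_m + sigma2_e), the model-based phenotypic-variance
#'   convention), `converged`, `boundary`, `n_eval`.
#' @export
fit_lmm_reml <- function(y, covariates = NULL, M, bounds = c(1e-6, 1e6),
                         tol = 1e-8, grid_n = 401L) {
  y <- as.numeric(y)
  n <- length(y)
  Mm <- as_M_matrix(M)
  if (nrow(Mm) != n) stop("dimensions of y and M disagree")
  if (any(!is.finite(y))) stop("y contains non-finite values")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (nrow(cv) != n) stop("covariates and y have different lengths")
    X <- cbind(X, cv)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("covariate design matrix is rank deficient")
  if (n <= p + 1L) stop("need n > rank(X) + 1 observations")
  stopifnot(length(bounds) == 2L, all(bounds > 0), bounds[1] < bounds[2])

  eg <- eigen(Mm, symmetric = TRUE)
  d <- pmax(eg$values, 0)  # clamp tiny negative eigenvalues of the PSD kernel
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  n_eval <- 0L
  f <- function(ll) {
    n_eval <<- n_eval + 1L
    reml_profile_point(ll, d, yt, Xt)$loglik
  }

  lo <- log(bounds[1]); hi <- log(bounds[2])
  grid <- seq(lo, hi, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))

  # Degenerate data (y in the column space of X): residual variance collapses.
  if (any(!is.finite(vals) & vals > 0) || all(vals == -Inf)) {
    beta_ols <- qr.coef(qr(X), y)
    return(structure(list(
      sigma2_m = 0, sigma2_e = 0, lambda = bounds[1],
      beta = stats::setNames(beta_ols, colnames(X)),
      loglik = NA_real_, microbiability = 0, sigma2_p_convention = "model",
      converged = TRUE, boundary = TRUE, degenerate = TRUE, n_eval = n_eval,
      sample_ids = rownames(Mm)), class = "variance_components"))
  }

  i <- which.max(vals)
  lwr <- grid[max(1L, i - 1L)]
  upr <- grid[min(grid_n, i + 1L)]
  if (lwr == upr) {
    opt_ll <- grid[i]
  } else {
    op <- stats::optimize(f, lower = lwr, upper = upr, maximum = TRUE, tol = tol)
    opt_ll <- if (op$objective >= vals[i]) op$maximum else grid[i]
  }
  fit <- reml_profile_point(opt_ll, d, yt, Xt)
  lambda <- exp(opt_ll)
  sigma2_e <- fit$sigma2_e
  sigma2_m <- lambda * sigma2_e
  boundary <- (opt_ll - lo) < 1e-6 * (hi - lo) || (hi - opt_ll) < 1e-6 * (hi - lo)
  structure(list(
    sigma2_m = sigma2_m, sigma2_e = sigma2_e, lambda = lambda,
    beta = stats::setNames(fit$beta, colnames(X)),
    loglik = fit$loglik,
    microbiability = lambda / (1 + lambda),
    sigma2_p_convention = "model",  # sigma2_p = sigma2_m + sigma2_e
    converged = TRUE, boundary = boundary, degenerate = FALSE,
    n_eval = n_eval, sample_ids = rownames(Mm)),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("variance_components: sigma2_m = %.4g, sigma2_e = %.4g, ",
                     "microbiability = %.3f%s\n"),
              x$sigma2_m, x$sigma2_e, x$microbiability,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

#' Microbiability ratio from fitted variance components
#'
#' Returns sigma2_m / (sigma2_m + sigma2_e): the fraction of phenotypic
#' variance attributable to microbial composition, under the model-based
#' phenotypic-variance convention (recorded in the fit as
#' `sigma2_p_convention`).
#'
#' @param vc A `variance_components` object, or a list with `sigma2_m` and
#'   `sigma2_e`.
#' @return A fraction in `[0, 1]`.
#' @export
microbiability <- function(vc) {
  s2m <- vc$sigma2_m; s2e <- vc$sigma2_e
  stopifnot(is.numeric(s2m), is.numeric(s2e), s2m >= 0, s2e >= 0)
  tot <- s2m + s2e
  if (tot == 0) stop("sigma2_m + sigma2_e = 0: microbiability undefined")
  s2m / tot
}

#' Parametric bootstrap for the microbiability estimate
#'
#' Simulates phenotypes from the fitted model (fixed effects + microbial and
#' residual components at their REML estimates), refits, and returns the
#' distribution of re-estimated microbiability values. No standard error is
#' attached to the point estimate by default; this is an optional add-on.
#'
#' @param vc A fitted `variance_components` object.
#' @param covariates Covariate matrix used in the original fit (or `NULL`).
#' @param M The `relationship_matrix` used in the original fit.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Numeric vector of bootstrap microbiability estimates, with the
#'   bootstrap standard error as attribute `"se"`.
#' @export
microbiability_bootstrap <- function(vc, covariates = NULL, M, n_boot = 50L,
                                     seed = 1L) {
  Mm <- as_M_matrix(M)
  n <- nrow(Mm)
  X <- cbind(1, if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates)))
  mu <- drop(X %*% vc$beta)
  eg <- eigen(Mm, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  est <- with_seed(substream_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(b) {
      m <- drop(eg$vectors %*% (sqrt(vc$sigma2_m * d) * rnorm(n)))
      yb <- mu + m + rnorm(n, sd = sqrt(vc$sigma2_e))
      fit_lmm_reml(yb, covariates, Mm, grid_n = 101L)$microbiability
    }, numeric(1))
  })
  attr(est, "se") <- stats::sd(est)
  est
}
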