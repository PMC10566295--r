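#' Fit ridge-regression BLUP of marker effects by spectral REML
#'
#' Fits `y = 1 mu + Z u + e` with `u ~ N(0, su2 I)` over all markers (the
#' common-variance normal prior) and `e ~ N(0, se2 I)`, where `Z` is the
#' column-centred dosage matrix. The variance ratio `lambda = se2 / su2`
#' is estimated by restricted maximum likelihood: the restricted
#' log-likelihood is profiled through the spectral decomposition of the
#' marker cross-product `Z Z'` projected off the intercept, and maximised
#' over `log(lambda)` on `[-10, 10]` to tolerance 1e-8. Marker effects are
#' the ridge solution at the optimum,
#' `u = Z' (Z Z' + lambda I)^{-1} (y - mu)`, equivalently
#' `(Z'Z + lambda I)^{-1} Z' (y - mu)`.
#'
#' @param g a `GenotypeMatrix` or dosage matrix without missing values;
#'   rows must be named by line id.
#' @param y per-line phenotype (typically a multi-environment BLUP),
#'   named by line id or aligned with the rows of `g`; length >= 3.
#' @param lambda optional fixed variance ratio; skips REML when given.
#' @return an object of class `GSFit` with `model = "rrBLUP"`,
#'   `intercept` (GLS estimate of mu), `marker_effects` (named),
#'   `variance_components` (`sigma2_u`, `sigma2_e`, `lambda`),
#'   `marker_ids`, `centers` (training column means used for prediction)
#'   and `reml` (the profiled criterion, for diagnostics).
#' @seealso [predict_gebv()], [fit_bayes()]
#' @export
fit_rrblup <- function(g, y, lambda = NULL) {
  d <- as_dosage_matrix(g)
  if (anyNA(d)) stop("missing dosages; impute first")
  y <- align_phenotype(y, rownames(d))
  n <- nrow(d)
  # REML needs residual degrees of freedom; a fixed lambda only needs the
  # ridge system to be solvable
  if (n < 3 && is.null(lambda)) stop("need at least 3 lines")
  if (n < 2) stop("need at least 2 lines")
  centers <- colMeans(d)
  Z <- sweep(d, 2, centers)

  if (stats::var(y) == 0) {
    return(new_gsfit("rrBLUP", intercept = mean(y),
                     effects = stats::setNames(numeric(ncol(d)), colnames(d)),
                     vc = list(sigma2_u = 0, sigma2_e = 0, lambda = Inf),
                     centers = centers))
  }

  K <- tcrossprod(Z)
  if (is.null(lambda)) {
    # project off the intercept and eigendecompose; the offset keeps the
    # null direction identifiable in the decomposition
    offset <- n
    P <- diag(n) - matrix(1 / n, n, n)
    eg <- eigen(P %*% (K + offset * diag(n)) %*% P, symmetric = TRUE)
    theta <- eg$values[seq_len(n - 1)] - offset
    theta[theta < 0] <- 0
    eta <- as.vector(crossprod(eg$vectors[, seq_len(n - 1)], y))
    crit <- function(loglam) {
      lam <- exp(loglam)
      (n - 1) * log(sum(eta^2 / (theta + lam))) + sum(log(theta + lam))
    }
    opt <- stats::optimize(crit, c(-10, 10), tol = 1e-8)
    lambda <- exp(opt$minimum)
    sigma2_u <- sum(eta^2 / (theta + lambda)) / (n - 1)
    reml <- list(criterion = crit, log_lambda = opt$minimum,
                 theta = theta, eta = eta)
  } else {
    sigma2_u <- NA_real_
    reml <- NULL
  }

  H <- K + lambda * diag(n)
  Hi1 <- solve(H, rep(1, n))
  mu <- sum(Hi1 * y) / sum(Hi1)
  u <- as.vector(crossprod(Z, solve(H, y - mu)))
  if (is.na(sigma2_u)) {
    # fixed-lambda path: method-of-moments residual variance
    fitted <- mu + as.vector(Z %*% u)
    sigma2_u <- stats::var(u)
    sigma2_e <- stats::var(y - fitted)
  } else {
    sigma2_e <- lambda * sigma2_u
  }
  fit <- new_gsfit("rrBLUP", intercept = mu,
                   effects = stats::setNames(u, colnames(d)),
                   vc = list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                             lambda = lambda),
                   centers = centers)
  fit$reml <- reml
  fit
}

# align a (possibly named) phenotype vector with the genotype lines
align_phenotype <- function(y, ids) {
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y)))
      stop("phenotype is missing values for some genotyped lines")
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop("unnamed phenotype must match the number of lines")
  }
  if (anyNA(y)) stop("missing phenotype values")
  as.numeric(y)
}

new_gsfit <- function(model, intercept, effects, vc, centers, mcmc = NULL) {
  structure(list(model = model, intercept = intercept,
                 marker_effects = effects,
                 variance_components = vc,
                 marker_ids = names(effects),
                 centers = centers, mcmc_meta = mcmc),
            class = "GSFit")
}

#' @export
print.GSFit <- function(x, ...) {
  cat(sprintf("GSFit [%s]: %d markers, intercept %.4g\n",
              x$model, length(x$marker_effects), x$intercept))
  vc <- x$variance_components
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(vc), unlist(vc)), collapse = ", "),
      "\n")
  if (!is.null(x$mcmc_meta))
    cat(sprintf("  MCMC: %d iterations, %d burn-in, thin %d, seed %d\n",
                x$mcmc_meta$iters, x$mcmc_meta$burnin, x$mcmc_meta$thin,
                x$mcmc_meta$seed))
  invisible(x)
}

#' Genomic estimated breeding values from a fitted model
#'
#' Exact linear scoring: `gebv_i = intercept + sum_k (dosage_ik -
#' center_k) * effect_k`, with the centring taken from the training fit.
#' Applied to the training matrix this reproduces the in-sample fitted
#' genetic values.
#'
#' @param fit a `GSFit` from [fit_rrblup()] or [fit_bayes()].
#' @param g_new a `GenotypeMatrix` or dosage matrix whose markers cover
#'   `fit$marker_ids`; extra markers are ignored, missing markers are an
#'   error.
#' @return a data frame `line_id`, `gebv`.
#' @export
predict_gebv <- function(fit, g_new) {
  d <- as_dosage_matrix(g_new)
  if (anyNA(d)) stop("missing dosages; impute first")
  miss <- setdiff(fit$marker_ids, colnames(d))
  if (length(miss))
    stop("genotypes lack ", length(miss), " marker(s) used in the fit")
  d <- d[, fit$marker_ids, drop = FALSE]
  gebv <- fit$intercept +
    as.vector(sweep(d, 2, fit$centers) %*% fit$marker_effects)
  data.frame(line_id = rownames(d), gebv = gebv, stringsAsFactors = FALSE)
}
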