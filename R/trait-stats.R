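#' Husk tightness index
#'
#' `HTI = (loose - tight) / loose * 100` (percent): the relative slack of
#' the husk around the ear; larger values mean a looser husk. When
#' measurement repeats are supplied as vectors, HTI is computed per repeat
#' and averaged.
#'
#' @param loose_perimeter loose husk perimeter(s), cm, > 0.
#' @param tight_perimeter tight husk perimeter(s), cm, must not exceed the
#'   loose perimeter (the tightened husk cannot be larger than the natural
#'   one).
#' @return HTI in percent, in `[0, 100]` (mean over repeats if vectors).
#' @examples
#' compute_hti(10, 8) # 20
#' @export
compute_hti <- function(loose_perimeter, tight_perimeter) {
  if (length(loose_perimeter) != length(tight_perimeter))
    stop("perimeter vectors must have equal length")
  if (any(loose_perimeter <= 0)) stop("loose perimeter must be positive")
  if (any(tight_perimeter > loose_perimeter))
    stop("tight perimeter exceeds loose perimeter")
  if (any(tight_perimeter < 0)) stop("perimeters must be non-negative")
  mean((loose_perimeter - tight_perimeter) / loose_perimeter * 100)
}

#' Area under the dry-down curve
#'
#' Trapezoidal integral of moisture readings over measurement days:
#' `sum_i (gamma_i + gamma_{i+1}) / 2 * (t_{i+1} - t_i)`. Linear in the
#' readings and additive over contiguous sub-intervals.
#'
#' @param days measurement days after pollination, strictly increasing,
#'   length >= 2.
#' @param readings converted moisture-meter readings, same length.
#' @return the trapezoidal area.
#' @examples
#' compute_auddc(c(0, 1, 2), c(2, 4, 6)) # 8
#' @export
compute_auddc <- function(days, readings) {
  n <- length(days)
  if (n < 2) stop("need at least 2 measurements")
  if (length(readings) != n) stop("days and readings must have equal length")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  sum((readings[-n] + readings[-1]) / 2 * diff(days))
}

#' AUDDC per line from a long moisture table
#'
#' @param series a data frame `line_id`, `day`, `reading` (e.g. from
#'   [simulate_moisture_series()]).
#' @return named numeric vector of AUDDC values per line.
#' @export
auddc_by_line <- function(series) {
  stopifnot(all(c("line_id", "day", "reading") %in% names(series)))
  vapply(split(series, series$line_id), function(s) {
    s <- s[order(s$day), ]
    compute_auddc(s$day, s$reading)
  }, numeric(1))
}

#' Broad-sense heritability from variance components
#'
#' Plug-in ratio `h2 = sg2 / (sg2 + sge2/e + se2/(r e))` for `e`
#' environments and `r` replicates per environment.
#'
#' @param v a list (or `VarianceComponents`) with elements `sigma2_g`,
#'   `sigma2_ge`, `sigma2_e`, `n_env`, `n_rep`.
#' @return heritability in `[0, 1]`.
#' @examples
#' estimate_heritability(variance_components(2, 3, 6, n_env = 3, n_rep = 2)) # 0.5
#' @export
estimate_heritability <- function(v) {
  denom <- v$sigma2_g + v$sigma2_ge / v$n_env +
    v$sigma2_e / (v$n_rep * v$n_env)
  if (denom <= 0) stop("all variance components are zero")
  v$sigma2_g / denom
}

#' Construct a variance-components record
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param sigma2_ge genotype-by-environment variance (>= 0).
#' @param sigma2_e residual variance (>= 0).
#' @param n_env,n_rep environments and replicates per environment.
#' @param mu overall mean.
#' @return a list of class `VarianceComponents`.
#' @export
variance_components <- function(sigma2_g, sigma2_ge, sigma2_e,
                                n_env, n_rep, mu = NA_real_) {
  if (any(c(sigma2_g, sigma2_ge, sigma2_e) < 0))
    stop("variance components must be non-negative")
  if (n_env < 1 || n_rep < 1) stop("n_env and n_rep must be >= 1")
  structure(list(sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
                 sigma2_e = sigma2_e, n_env = n_env, n_rep = n_rep,
                 mu = mu),
            class = "VarianceComponents")
}

#' Multi-environment BLUP of line genotypic values
#'
#' Fits the mixed model `y_ijk = mu + e_i + r(e)_ij + f_k + (f x e)_ik +
#' eps_ijk` by REML, with environment and replicate-within-environment as
#' fixed effects and line and line-by-environment as random effects. The
#' per-line BLUP is the overall phenotype mean plus the predicted line
#' effect, so BLUPs shrink toward the mean as the genotypic signal
#' weakens.
#'
#' With a single environment the GxE component cannot be separated and is
#' dropped with a warning. With a single observation per line (one
#' environment, one replicate) line and residual variance are not
#' separable; the observations themselves are returned as BLUPs with a
#' warning (the no-noise limit).
#'
#' @param p phenotype records: data frame with columns `line_id`, `env`,
#'   `rep`, `value`; `(line, env, rep)` keys must be unique.
#' @return a list of class `BlupResult` with `blup` (named vector of
#'   per-line BLUP values), `components` (a [variance_components()] with
#'   REML estimates; negative estimates are truncated at zero by REML
#'   itself) and `mu` (the overall mean added back).
#' @export
fit_environment_blup <- function(p) {
  stopifnot(all(c("line_id", "env", "rep", "value") %in% names(p)))
  if (anyDuplicated(p[, c("line_id", "env", "rep")]))
    stop("duplicate (line, environment, replicate) keys")
  lines <- unique(p$line_id)
  if (length(lines) < 2) stop("need at least 2 lines")
  n_env <- length(unique(p$env))
  # mean replicates per (line, env) cell, for the heritability denominator
  n_rep <- mean(table(p$line_id, p$env)[table(p$line_id, p$env) > 0])
  mu <- mean(p$value)

  if (stats::var(p$value) == 0) {
    comp <- variance_components(0, 0, 0, n_env, n_rep, mu)
    return(structure(list(blup = stats::setNames(rep(mu, length(lines)), lines),
                          components = comp, mu = mu, fit = NULL),
                     class = "BlupResult"))
  }
  if (nrow(p) == length(lines)) {
    warning("one observation per line: line and residual variance are not ",
            "separable; returning observations as BLUPs")
    b <- stats::setNames(p$value, p$line_id)[lines]
    comp <- variance_components(stats::var(p$value), 0, 0, n_env, n_rep, mu)
    return(structure(list(blup = b, components = comp, mu = mu, fit = NULL),
                     class = "BlupResult"))
  }

  dat <- data.frame(line = factor(p$line_id, levels = lines),
                    env_rep = interaction(p$env, p$rep, drop = TRUE),
                    line_env = interaction(p$line_id, p$env, drop = TRUE),
                    value = p$value)
  with_ge <- n_env >= 2
  if (!with_ge)
    warning("single environment: fitting without a GxE component")
  form <- if (with_ge)
    value ~ env_rep + (1 | line) + (1 | line_env) else
    value ~ env_rep + (1 | line)
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  comp <- variance_components(get_vc("line"),
                              if (with_ge) get_vc("line_env") else 0,
                              get_vc("Residual"), n_env, n_rep, mu)
  re <- lme4::ranef(fit)$line
  blup <- stats::setNames(mu + re[lines, 1], lines)
  structure(list(blup = blup, components = comp, mu = mu, fit = fit),
            class = "BlupResult")
}

#' @export
print.BlupResult <- function(x, ...) {
  h2 <- tryCatch(estimate_heritability(x$components), error = function(e) NA)
  cat(sprintf(paste0("Multi-environment BLUP: %d lines, %d env x ~%.1f rep; ",
                     "sg2 = %.3g, sge2 = %.3g, se2 = %.3g (h2 = %.3f)\n"),
              length(x$blup), x$components$n_env, x$components$n_rep,
              x$components$sigma2_g, x$components$sigma2_ge,
              x$components$sigma2_e, h2))
  invisible(x)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return a list with `r` (correlation), `p` (two-sided p-value from the
#'   t distribution with n - 2 df) and `n`.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
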