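#' Simulate a quantitative trait over a multi-environment trial
#'
#' Draws additive QTL effects on the simulated panel and generates
#' phenotype records `y_ijk = mu + e_i + r(e)_ij + f_k + (f x e)_ik +
#' eps_ijk` for `n_env` environments x `n_rep` replicates. Genetic values
#' are standardised to variance 1 and the genotype-by-environment and
#' residual variances are scaled so that the broad-sense heritability
#' `h2 = sg2 / (sg2 + sge2/e + se2/(r e))` equals `cfg$h2_target` in
#' expectation. True breeding values are recorded before any noise is
#' added. With `h2_target = 0` the genetic term is omitted entirely (the
#' phenotype is pure noise) while the TBV is still recorded.
#'
#' @param g an imputed `GenotypeMatrix` (no missing calls).
#' @param panel a [line_panel()] covering the lines of `g`.
#' @param cfg a [simulation_config()].
#' @param architecture `"polygenic"` (many small Gaussian effects; default
#'   `n_qtl = 0.5 * n_markers`) or `"oligogenic"` (few large effects;
#'   default `n_qtl = 10`, capped at 20).
#' @return a list with `phenotypes` (data frame `line_id`, `env`, `rep`,
#'   `value`) and `truth` (a `SimTruth`: `qtl_ids`, `qtl_effects` over all
#'   markers, `tbv`, `realized_h2`, plus the variance components used).
#' @export
simulate_trait <- function(g, panel, cfg,
                           architecture = c("polygenic", "oligogenic")) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  architecture <- match.arg(architecture)
  d <- as_dosage_matrix(g)
  if (anyNA(d)) stop("genotypes must be imputed before trait simulation")
  set.seed(derive_seed(cfg$seed, "trait", architecture))
  m <- ncol(d)
  n_qtl <- cfg$n_qtl %||%
    if (architecture == "oligogenic") 10L else max(1L, round(0.5 * m))
  if (architecture == "oligogenic" && n_qtl > 20)
    stop("oligogenic architecture expects n_qtl <= 20")
  if (cfg$h2_target == 0 && n_qtl == 0)
    stop("n_qtl = 0 with h2_target = 0 leaves no trait to simulate")

  qtl_idx <- sort(sample.int(m, n_qtl))
  effects <- numeric(m)
  effects[qtl_idx] <- if (architecture == "oligogenic")
    stats::rnorm(n_qtl, 0, 1) else stats::rnorm(n_qtl, 0, 1 / sqrt(n_qtl))
  tbv <- as.vector(d %*% effects)
  sd_tbv <- stats::sd(tbv)
  if (sd_tbv > 0) {
    effects <- effects / sd_tbv # unit genetic variance
    tbv <- tbv / sd_tbv
  } else if (cfg$h2_target > 0) {
    stop("simulated genetic values have zero variance; cannot reach ",
         "h2_target > 0 (monomorphic QTL?)")
  }
  f <- tbv - mean(tbv)

  e <- cfg$n_env; r <- cfg$n_rep
  sigma2_g <- if (cfg$h2_target > 0) stats::var(f) else 0
  sigma2_ge <- cfg$gxe_var_frac * sigma2_g
  sigma2_e <- if (cfg$h2_target > 0) {
    s <- r * e * (sigma2_g / cfg$h2_target - sigma2_g - sigma2_ge / e)
    if (s < 0)
      stop("h2_target unreachable with gxe_var_frac = ", cfg$gxe_var_frac)
    s
  } else 1

  n <- nrow(d)
  mu <- 15 # HTI-like percentage scale
  env_eff <- stats::rnorm(e, 0, 1)
  rep_eff <- matrix(stats::rnorm(e * r, 0, 0.5), e, r)
  ge <- matrix(stats::rnorm(n * e, 0, sqrt(sigma2_ge)), n, e)
  gen <- if (cfg$h2_target > 0) f else rep(0, n)

  recs <- expand.grid(rep = seq_len(r), env = seq_len(e), line = seq_len(n))
  eps <- stats::rnorm(nrow(recs), 0, sqrt(sigma2_e))
  value <- mu + env_eff[recs$env] + rep_eff[cbind(recs$env, recs$rep)] +
    gen[recs$line] + ge[cbind(recs$line, recs$env)] + eps
  phen <- data.frame(line_id = rownames(d)[recs$line],
                     env = paste0("E", recs$env),
                     rep = paste0("R", recs$rep),
                     value = value, stringsAsFactors = FALSE)

  realized <- if (cfg$h2_target > 0) {
    vg <- stats::var(f); vge <- stats::var(as.vector(ge))
    ve <- stats::var(eps)
    vg / (vg + vge / e + ve / (r * e))
  } else 0
  truth <- structure(list(
    qtl_ids = colnames(d)[qtl_idx],
    qtl_effects = stats::setNames(effects, colnames(d)),
    tbv = stats::setNames(tbv, rownames(d)),
    realized_h2 = realized,
    sigma2_g = sigma2_g, sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
    n_env = e, n_rep = r
  ), class = "SimTruth")
  list(phenotypes = phen, truth = truth)
}

#' Simulate kernel-moisture dry-down series tied to husk tightness
#'
#' Generates, per line, a declining moisture-reading curve over the given
#' measurement days whose area under the dry-down curve (AUDDC) correlates
#' with the supplied husk-tightness values at a target correlation within
#' each subgroup — e.g. negative for temperate subgroups and near zero for
#' tropical material. Each line's curve is a linear decline from a latent
#' starting level plus small measurement noise, so AUDDC is (almost) a
#' linear function of the latent level and the target correlation is
#' realized up to sampling error.
#'
#' @param tbv_hti named numeric vector of per-line HTI-like values
#'   (names = line ids).
#' @param panel a [line_panel()] covering those lines.
#' @param target_corr either a single correlation in `[-1, 1]` applied to
#'   all subgroups, or a named vector/list per subgroup.
#' @param days measurement days after pollination, strictly increasing,
#'   length >= 2 (default `c(34, 40, 46, 52, 58)`).
#' @param seed integer seed.
#' @return a data frame `line_id`, `day`, `reading` of class
#'   `MoistureSeries` (long format; use [auddc_by_line()] to reduce it).
#' @export
simulate_moisture_series <- function(tbv_hti, panel,
                                     target_corr = -0.5,
                                     days = c(34, 40, 46, 52, 58),
                                     seed = 1) {
  if (length(days) < 2) stop("need at least 2 measurement days")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (is.null(names(tbv_hti))) stop("tbv_hti must be named by line id")
  rho_all <- if (length(target_corr) == 1 && is.null(names(target_corr)))
    stats::setNames(rep(as.numeric(target_corr), 4), subgroup_levels()) else
      unlist(target_corr)
  if (any(abs(rho_all) > 1)) stop("target correlations must lie in [-1, 1]")
  set.seed(seed)
  out <- vector("list", length(tbv_hti))
  sg <- panel$subgroup[match(names(tbv_hti), panel$line_id)]
  if (anyNA(sg)) stop("panel does not cover all lines in tbv_hti")
  level <- numeric(length(tbv_hti))
  for (s in unique(sg)) {
    ix <- which(sg == s)
    rho <- rho_all[[s]] %||% 0
    z <- if (stats::sd(tbv_hti[ix]) > 0)
      as.vector(scale(tbv_hti[ix])) else rep(0, length(ix))
    a <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(ix))
    level[ix] <- 42 + 3 * a
  }
  decline <- 0.7 # percentage points of moisture per day
  for (i in seq_along(tbv_hti)) {
    readings <- level[i] - decline * (days - days[1]) +
      stats::rnorm(length(days), 0, 0.3)
    out[[i]] <- data.frame(line_id = names(tbv_hti)[i], day = days,
                           reading = readings, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("MoistureSeries", "data.frame"))
}
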