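#' Prediction ability: Pearson correlation of GEBV with observed values
#'
#' The standard genomic-prediction accuracy measure: the Pearson
#' correlation between genomic estimated breeding values and the observed
#' (or true, in simulation) values of the testing lines.
#'
#' @param gebv a data frame `line_id`, `gebv` (from [predict_gebv()]) or a
#'   named numeric vector.
#' @param observed named numeric vector of observed/true values.
#' @return the Pearson correlation, in `[-1, 1]`.
#' @export
prediction_ability <- function(gebv, observed) {
  if (is.data.frame(gebv))
    gebv <- stats::setNames(gebv$gebv, gebv$line_id)
  if (is.null(names(gebv)) || is.null(names(observed)))
    stop("gebv and observed must be named by line id")
  ids <- intersect(names(gebv), names(observed))
  if (length(ids) < 3) stop("need at least 3 overlapping lines")
  x <- gebv[ids]; y <- observed[ids]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector; prediction ability undefined")
  stats::cor(x, y)
}

#' Define a cross-validation scheme
#'
#' @param test_fraction fraction of the sampling frame held out as the
#'   testing population, in (0, 1). Training-proportion sweeps
#'   conventionally use the grid 0.1 to 0.9 in steps of 0.1.
#' @param n_repeats number of Monte-Carlo repeats (default 100).
#' @param scope `"whole_panel"`, `"within_subgroup"` or
#'   `"across_subgroup"`.
#' @param focal_subgroup subgroup label; required for the subgroup scopes
#'   and forbidden for `whole_panel`.
#' @param seed master seed; per-repeat seeds are derived deterministically
#'   from it, so results do not depend on execution order.
#' @return a list of class `CVScheme`.
#' @export
cv_scheme <- function(test_fraction, n_repeats = 100,
                      scope = c("whole_panel", "within_subgroup",
                                "across_subgroup"),
                      focal_subgroup = NULL, seed = 1) {
  scope <- match.arg(scope)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (scope == "whole_panel" && !is.null(focal_subgroup))
    stop("whole_panel scope forbids a focal subgroup")
  if (scope != "whole_panel") {
    if (is.null(focal_subgroup))
      stop(scope, " scope requires a focal subgroup")
    if (!focal_subgroup %in% subgroup_levels())
      stop("unknown subgroup: ", focal_subgroup)
  }
  structure(list(test_fraction = test_fraction, n_repeats = n_repeats,
                 scope = scope, focal_subgroup = focal_subgroup,
                 seed = seed),
            class = "CVScheme")
}

# unified model dispatcher used by the CV engine; extra arguments not
# understood by the target fitter (e.g. MCMC lengths passed to rrBLUP in a
# mixed-model sweep) are dropped silently
fit_gs_model <- function(d, y, model, seed, model_args = list()) {
  if (tolower(model) %in% c("rrblup", "rr-blup")) {
    args <- model_args[names(model_args) %in% names(formals(fit_rrblup))]
    do.call(fit_rrblup, c(list(g = d, y = y), args))
  } else {
    args <- model_args[names(model_args) %in% names(formals(fit_bayes))]
    do.call(fit_bayes, c(list(g = d, y = y, model = model, seed = seed),
                         args))
  }
}

#' Monte-Carlo cross-validation of a GS model on the whole panel
#'
#' Each repeat draws a uniform random testing set of size
#' `round(test_fraction * n)` (half away from zero) without replacement,
#' fits the model on the complement, scores the testing lines and records
#' the prediction ability. Training and testing sets are disjoint and
#' exhaustive of the panel in every repeat; per-repeat seeds are derived
#' from the scheme seed so the abilities vector is reproducible.
#'
#' @param g a `GenotypeMatrix` or dosage matrix, imputed.
#' @param y named per-line values: multi-environment BLUPs on real data,
#'   or true breeding values in simulation.
#' @param model `"rrblup"` or a Bayesian model name for [fit_bayes()].
#' @param scheme a [cv_scheme()] with scope `whole_panel`.
#' @param model_args extra arguments passed to the model fitter (e.g.
#'   `iters` for Bayesian models).
#' @param truth optional named vector of true breeding values; when given,
#'   testing lines are scored against it instead of `y` (the simulation
#'   TBV substitution), while the model is still trained on `y`.
#' @param cell_id internal label mixed into per-repeat seeds by
#'   [factorial_run()].
#' @return a list of class `CVResult`: `abilities` (per repeat),
#'   `mean_ability`, `sd_ability`, `model`, `scheme`.
#' @export
run_cv <- function(g, y, model = "rrblup", scheme,
                   model_args = list(), truth = NULL, cell_id = "whole") {
  stopifnot(inherits(scheme, "CVScheme"))
  if (scheme$scope != "whole_panel")
    stop("use run_subgroup_cv() for subgroup scopes")
  d <- as_dosage_matrix(g)
  y <- align_phenotype(y, rownames(d))
  names(y) <- rownames(d)
  target <- if (is.null(truth)) y else
    stats::setNames(align_phenotype(truth, rownames(d)), rownames(d))
  n <- nrow(d)
  n_test <- as.integer(round_half_up(scheme$test_fraction * n))
  if (n_test < 3) stop("testing set smaller than 3 lines")
  if (n - n_test < 3) stop("training set smaller than 3 lines")

  # sample from the id-sorted frame so results are invariant to the
  # ordering of lines in the input
  pool <- sort(rownames(d))
  abilities <- vapply(seq_len(scheme$n_repeats), function(r) {
    s <- derive_seed(scheme$seed, cell_id, model, r)
    set.seed(s)
    test <- match(pool[sample.int(n, n_test)], rownames(d))
    fit <- fit_gs_model(d[-test, , drop = FALSE], y[-test], model,
                        seed = derive_seed(s, "chain"),
                        model_args = model_args)
    pred <- predict_gebv(fit, d[test, , drop = FALSE])
    prediction_ability(pred, target[test])
  }, numeric(1))
  new_cv_result(abilities, model, scheme)
}

#' Cross-validation with the training set sampled from one subgroup
#'
#' The training population is a random fraction `1 - test_fraction` of
#' the focal subgroup. With scope `within_subgroup` the testing set is
#' the remainder of that subgroup; with `across_subgroup` it is the
#' remainder plus every line of the other subgroups.
#'
#' @inheritParams run_cv
#' @param panel a [line_panel()] covering the lines of `g`.
#' @param scheme a [cv_scheme()] with scope `within_subgroup` or
#'   `across_subgroup`.
#' @return a `CVResult` (see [run_cv()]).
#' @export
run_subgroup_cv <- function(g, y, panel, model = "rrblup", scheme,
                            model_args = list(), truth = NULL,
                            cell_id = "subgroup") {
  stopifnot(inherits(scheme, "CVScheme"))
  if (scheme$scope == "whole_panel")
    stop("use run_cv() for whole-panel schemes")
  d <- as_dosage_matrix(g)
  y <- align_phenotype(y, rownames(d))
  names(y) <- rownames(d)
  target <- if (is.null(truth)) y else
    stats::setNames(align_phenotype(truth, rownames(d)), rownames(d))
  focal_ids <- sort(intersect(
    rownames(d), panel$line_id[panel$subgroup == scheme$focal_subgroup]))
  focal <- match(focal_ids, rownames(d))
  if (length(focal) < 10)
    stop("focal subgroup has fewer than 10 lines")
  n_train <- as.integer(round_half_up((1 - scheme$test_fraction) *
                                        length(focal)))
  if (n_train < 3) stop("training set smaller than 3 lines")
  if (length(focal) - n_train < 3 && scheme$scope == "within_subgroup")
    stop("focal-subgroup remainder smaller than 3 lines")

  abilities <- vapply(seq_len(scheme$n_repeats), function(r) {
    s <- derive_seed(scheme$seed, cell_id, scheme$scope,
                     scheme$focal_subgroup, model, r)
    set.seed(s)
    train <- match(focal_ids[sample.int(length(focal_ids), n_train)],
                   rownames(d))
    test <- if (scheme$scope == "within_subgroup")
      setdiff(focal, train) else
      setdiff(seq_len(nrow(d)), train)
    fit <- fit_gs_model(d[train, , drop = FALSE], y[train], model,
                        seed = derive_seed(s, "chain"),
                        model_args = model_args)
    pred <- predict_gebv(fit, d[test, , drop = FALSE])
    prediction_ability(pred, target[test])
  }, numeric(1))
  new_cv_result(abilities, model, scheme)
}

new_cv_result <- function(abilities, model, scheme) {
  structure(list(abilities = abilities,
                 mean_ability = mean(abilities),
                 sd_ability = stats::sd(abilities),
                 model = model, scheme = scheme),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(paste0("CVResult [%s, %s%s]: test fraction %.2f, %d repeats; ",
                     "mean ability %.4f (sd %.4f)\n"),
              x$model, x$scheme$scope,
              if (is.null(x$scheme$focal_subgroup)) "" else
                paste0(":", x$scheme$focal_subgroup),
              x$scheme$test_fraction, length(x$abilities),
              x$mean_ability, x$sd_ability))
  invisible(x)
}

#' Factorial cross-validation over marker sets, densities, models and schemes
#'
#' Executes the full cross-product of marker sets x LD densities x models
#' x CV schemes with independent derived seeds per cell, streaming the
#' per-repeat prediction abilities into one tidy table. A cell that fails
#' its own preconditions (e.g. a subgroup too small for the fraction) is
#' recorded as failed, not fatal.
#'
#' @param g_sets named list of `GenotypeMatrix` objects (platform tag ->
#'   marker set), each sorted by (chrom, pos) and imputed.
#' @param y named per-line values.
#' @param models character vector of model names.
#' @param densities numeric vector of LD r-squared thresholds; each
#'   marker set is pruned once per density via [prune_by_ld()].
#' @param schemes list of [cv_scheme()] objects.
#' @param panel a [line_panel()]; required if any scheme has a subgroup
#'   scope.
#' @param model_args extra arguments passed to the model fitters.
#' @param truth optional named TBV vector passed through to the CV
#'   runners.
#' @return a data frame with columns `platform_tag`, `model`,
#'   `density_r2`, `scope`, `focal_subgroup`, `test_fraction`, `repeat_idx`,
#'   `ability`, plus attribute `failed` listing failed cells.
#' @export
factorial_run <- function(g_sets, y, models = "rrblup",
                          densities = 1.0, schemes, panel = NULL,
                          model_args = list(), truth = NULL) {
  if (is.null(names(g_sets))) stop("g_sets must be a named list")
  if (inherits(schemes, "CVScheme")) schemes <- list(schemes)
  rows <- list(); failed <- list()
  for (tag in names(g_sets)) {
    for (dens in densities) {
      gp <- prune_by_ld(g_sets[[tag]], dens)$genotype
      for (model in models) {
        for (sc in schemes) {
          cell <- paste(tag, model, dens, sc$scope,
                        sc$focal_subgroup %||% "-", sc$test_fraction,
                        sep = "|")
          res <- tryCatch({
            if (sc$scope == "whole_panel")
              run_cv(gp, y, model, sc, model_args, truth = truth,
                     cell_id = cell)
            else
              run_subgroup_cv(gp, y, panel, model, sc, model_args,
                              truth = truth, cell_id = cell)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failed[[cell]] <- conditionMessage(res)
            next
          }
          rows[[cell]] <- data.frame(
            platform_tag = tag, model = model, density_r2 = dens,
            scope = sc$scope,
            focal_subgroup = sc$focal_subgroup %||% NA_character_,
            test_fraction = sc$test_fraction,
            repeat_idx = seq_along(res$abilities),
            ability = res$abilities, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "failed") <- failed
  out
}
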