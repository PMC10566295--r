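#' Filter markers by minor allele frequency and missingness
#'
#' Retains markers with MAF >= `maf_min` and missing rate <= `miss_max`
#' (both thresholds inclusive). MAF is computed from non-missing calls
#' only. Removal reasons are attributed by the first failing rule, MAF
#' checked before missingness, so the report counts are disjoint.
#'
#' @param g a `GenotypeMatrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missing-call rate (default 0.2).
#' @return a list with `genotype` (the filtered `GenotypeMatrix`) and
#'   `report` (a `MarkerQCReport`: counts `n_input`, `n_removed_maf`,
#'   `n_removed_missing`, `n_retained`, plus per-marker `maf` and
#'   `missing_rate`).
#' @export
filter_markers <- function(g, maf_min = 0.05, miss_max = 0.2) {
  if (!inherits(g, "GenotypeMatrix")) stop("'g' must be a GenotypeMatrix")
  if (n_markers(g) == 0) stop("empty genotype matrix")
  maf <- marker_maf(g)
  miss <- marker_missing_rate(g)
  # a fully-missing marker has undefined MAF; treat it as failing the MAF
  # rule only if it has calls, otherwise it fails the missing rule
  maf_ok <- !is.nan(maf) & maf >= maf_min
  fail_maf <- !is.nan(maf) & maf < maf_min
  fail_missing <- !fail_maf & (miss > miss_max | is.nan(maf))
  keep <- maf_ok & miss <= miss_max
  report <- structure(list(
    n_input = n_markers(g),
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_missing),
    n_retained = sum(keep),
    maf = maf,
    missing_rate = miss
  ), class = "MarkerQCReport")
  if (!any(keep))
    stop("all markers removed by QC (maf_min = ", maf_min,
         ", miss_max = ", miss_max, ")")
  list(genotype = g[, keep], report = report)
}

#' @export
print.MarkerQCReport <- function(x, ...) {
  cat(sprintf(paste0("Marker QC: %d input, %d removed (MAF), ",
                     "%d removed (missingness), %d retained\n"),
              x$n_input, x$n_removed_maf, x$n_removed_missing, x$n_retained))
  invisible(x)
}

#' Impute missing dosages marker by marker
#'
#' `marker_mean` replaces missing calls with the marker's mean dosage over
#' non-missing calls (possibly fractional); `marker_mode` with the most
#' frequent observed dosage (ties broken toward the smaller dosage).
#' Non-missing cells are never changed.
#'
#' @param g a `GenotypeMatrix`.
#' @param method `"marker_mean"` or `"marker_mode"`.
#' @return a `GenotypeMatrix` with no missing values.
#' @export
impute_missing <- function(g, method = c("marker_mean", "marker_mode")) {
  method <- match.arg(method)
  d <- g$dosages
  if (!anyNA(d)) return(g)
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing))
    stop(sum(all_missing), " marker(s) have no non-missing calls; ",
         "run filter_markers() first")
  fill <- if (method == "marker_mean") {
    colMeans(d, na.rm = TRUE)
  } else {
    apply(d, 2, function(x) {
      tab <- table(x[!is.na(x)])
      as.numeric(names(tab)[which.max(tab)]) # which.max takes first tie
    })
  }
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- fill[idx[, 2]]
  genotype_matrix(d, chrom = g$map$chrom, pos = g$map$pos,
                  ref = g$map$ref, alt = g$map$alt,
                  strict = (method == "marker_mode"))
}
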