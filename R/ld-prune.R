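#' Pairwise linkage disequilibrium (r-squared) between two markers
#'
#' Squared Pearson correlation of the two dosage vectors over lines
#' non-missing at both markers — the composite genotype-correlation LD
#' measure. Undefined (returned as `NA`) when either marker is
#' monomorphic on the shared lines.
#'
#' @param g a `GenotypeMatrix` or dosage matrix.
#' @param i,j marker indices or ids.
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_r2 <- function(g, i, j) {
  d <- as_dosage_matrix(g)
  xi <- d[, i]; xj <- d[, j]
  keep <- !is.na(xi) & !is.na(xj)
  xi <- xi[keep]; xj <- xj[keep]
  if (length(xi) < 2 || stats::sd(xi) == 0 || stats::sd(xj) == 0)
    return(NA_real_)
  stats::cor(xi, xj)^2
}

#' Prune markers by LD within sliding windows
#'
#' Greedy indep-pairwise-style pruning, per chromosome: within each
#' window of `window_size` markers, while any remaining pair exceeds the
#' r-squared threshold, the member of the worst pair with the higher mean
#' r-squared to all other remaining window markers is removed (ties broken
#' toward the later position); the window then advances by `step` markers.
#' A threshold of 1.0 is a no-op (no pair can exceed it), reproducing the
#' convention that full density means no pruning. Output marker order is
#' input order; the result is deterministic and idempotent.
#'
#' @param g a `GenotypeMatrix` with markers sorted by (chrom, pos); see
#'   [sort_markers()].
#' @param r2_threshold pairwise r-squared above which one of a pair is
#'   removed, in (0, 1].
#' @param window_size window width in markers (default 50).
#' @param step window advance in markers (default 5); must be smaller
#'   than `window_size`.
#' @return a list with `genotype` (pruned `GenotypeMatrix`) and `kept`
#'   (character vector of kept marker ids, in input order).
#' @export
prune_by_ld <- function(g, r2_threshold, window_size = 50, step = 5) {
  if (!inherits(g, "GenotypeMatrix")) stop("'g' must be a GenotypeMatrix")
  if (n_markers(g) == 0) stop("empty genotype matrix")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  if (step < 1 || window_size <= step)
    stop("need window_size > step >= 1")
  runs <- rle(g$map$chrom)
  pos_ok <- all(vapply(split(g$map$pos, g$map$chrom),
                       function(p) !is.unsorted(p), logical(1)))
  if (anyDuplicated(runs$values) || !pos_ok)
    stop("markers must be sorted by (chrom, pos); see sort_markers()")
  if (r2_threshold >= 1)
    return(list(genotype = g, kept = marker_ids(g)))

  d <- g$dosages
  keep <- rep(TRUE, ncol(d))
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    start <- 1
    repeat {
      win <- idx[seq(start, min(start + window_size - 1, length(idx)))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        keep[win] <- prune_window(d[, win, drop = FALSE],
                                  g$map$pos[win], r2_threshold)
      }
      if (start + window_size - 1 >= length(idx)) break
      start <- start + step
    }
  }
  list(genotype = g[, keep], kept = marker_ids(g)[keep])
}

# greedy removal within one window; returns logical keep vector
prune_window <- function(dw, pos, thr) {
  keep <- rep(TRUE, ncol(dw))
  suppressWarnings(r2 <- stats::cor(dw)^2) # NA for monomorphic columns
  diag(r2) <- 0
  r2[is.na(r2)] <- 0
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    sub <- r2[act, act, drop = FALSE]
    if (max(sub) <= thr) break
    # remove the member of some offending pair with the highest mean r2
    # to the other active markers; ties -> later position
    offenders <- unique(as.vector(which(sub > thr, arr.ind = TRUE)))
    mean_r2 <- rowMeans(sub[offenders, , drop = FALSE])
    worst <- offenders[order(-mean_r2, -pos[act][offenders])][1]
    keep[act[worst]] <- FALSE
  }
  keep
}

#' Sweep marker density over a grid of LD thresholds
#'
#' Runs [prune_by_ld()] at each threshold; kept-set sizes are
#' non-decreasing in the threshold and the threshold 1.0 keeps every
#' marker.
#'
#' @param g a filtered, imputed `GenotypeMatrix` sorted by (chrom, pos).
#' @param thresholds r-squared grid (default
#'   `c(0.01, 0.1, 0.2, 0.5, 0.8, 1.0)`).
#' @param ... passed to [prune_by_ld()].
#' @return a named list mapping each threshold to its kept marker ids.
#' @export
density_sweep <- function(g, thresholds = c(0.01, 0.1, 0.2, 0.5, 0.8, 1.0),
                          ...) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  out <- lapply(thresholds, function(t) prune_by_ld(g, t, ...)$kept)
  names(out) <- as.character(thresholds)
  out
}
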