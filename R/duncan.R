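#' Duncan's multiple range test with significance letters
#'
#' One-way comparison of group means using Duncan's protected studentized
#' ranges: the pooled error variance comes from a one-way ANOVA, and a
#' range of `p` consecutive ordered means is declared homogeneous when its
#' spread does not exceed `q(1 - (1-alpha)^(p-1), p, df) * sqrt(MSE / n_h)`
#' (`n_h` the harmonic mean group size). Ranges are examined from widest
#' to narrowest and a range inside a homogeneous one is never declared
#' significant (Duncan's protection rule). Letters are assigned to the
#' maximal homogeneous ranges, so groups sharing no letter differ
#' significantly at `alpha` and groups sharing a letter do not. Welch
#' pairwise t-tests are also reported as a robustness check.
#'
#' @param values numeric vector of observations (e.g. per-repeat
#'   prediction abilities).
#' @param groups group labels, same length.
#' @param alpha significance level (default 0.05).
#' @return a list of class `GroupComparison`: `groups` (data frame with
#'   `group`, `mean`, `n`, `letters`, ordered by decreasing mean),
#'   `alpha`, `df`, `mse`, and `welch_p` (matrix of pairwise Welch
#'   p-values).
#' @export
duncan_grouping <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  labs <- unique(groups)
  k <- length(labs)
  if (k < 2) stop("need at least 2 groups")
  ns <- table(groups)[labs]
  if (any(ns < 2)) stop("every group needs at least 2 observations")

  fit <- stats::aov(values ~ factor(groups))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df <- stats::df.residual(fit)
  if (mse <= 0 || mse < 1e-10 * max(stats::var(values), 1))
    stop("zero pooled error variance")
  n_h <- k / sum(1 / ns)
  se <- sqrt(mse / n_h)

  means <- tapply(values, groups, mean)[labs]
  ord <- order(-means)
  m_sorted <- means[ord]

  # critical range for a span of p ordered means, at Duncan's protection
  # level alpha_p = 1 - (1 - alpha)^(p - 1)
  crit <- function(p) stats::qtukey((1 - alpha)^(p - 1), p, df) * se

  # widest-to-narrowest examination with the protection rule
  homogeneous <- matrix(FALSE, k, k) # [i, j]: range i..j declared homogeneous
  for (p in k:2) {
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      covered <- FALSE
      if (p < k) {
        for (a in seq_len(i)) for (b in j:k)
          if ((b - a + 1) > p && homogeneous[a, b]) covered <- TRUE
      }
      if (covered) {
        homogeneous[i, j] <- TRUE
      } else if (m_sorted[i] - m_sorted[j] <= crit(p)) {
        homogeneous[i, j] <- TRUE
      }
    }
  }
  diag(homogeneous) <- TRUE

  # letters from maximal homogeneous ranges (ranges are intervals in the
  # sorted order, so maximal ranges give the letter classes)
  ranges <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homogeneous[i, j + 1]) j <- j + 1
    ranges[[i]] <- c(i, j)
  }
  ranges <- unique(ranges)
  maximal <- ranges[vapply(ranges, function(r) {
    !any(vapply(ranges, function(s)
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2]),
      logical(1)))
  }, logical(1))]
  lett <- rep("", k)
  for (li in seq_along(maximal)) {
    r <- maximal[[li]]
    lett[r[1]:r[2]] <- paste0(lett[r[1]:r[2]], letters[li])
  }

  welch <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    p <- stats::t.test(values[groups == labs[a]],
                       values[groups == labs[b]])$p.value
    welch[a, b] <- welch[b, a] <- p
  }

  structure(list(
    groups = data.frame(group = labs[ord], mean = unname(m_sorted),
                        n = as.integer(ns[ord]), letters = lett,
                        stringsAsFactors = FALSE),
    alpha = alpha, df = df, mse = mse, welch_p = welch
  ), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, df = %d)\n",
              x$alpha, x$df))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Do two groups differ under a grouping-letter assignment?
#'
#' @param gc a `GroupComparison` from [duncan_grouping()].
#' @param a,b group labels.
#' @return `TRUE` if the groups share no letter.
#' @export
groups_differ <- function(gc, a, b) {
  la <- strsplit(gc$groups$letters[gc$groups$group == a], "")[[1]]
  lb <- strsplit(gc$groups$letters[gc$groups$group == b], "")[[1]]
  length(intersect(la, lb)) == 0
}
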