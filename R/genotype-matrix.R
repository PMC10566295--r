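#' Construct a genotype matrix
#'
#' The central genotype container: a lines x markers numeric matrix of
#' alt-allele dosages together with per-marker map information. Raw dosages
#' are 0, 1, 2 or `NA` (missing); after mean imputation fractional dosages
#' in `[0, 2]` are allowed.
#'
#' @param dosages numeric matrix, lines in rows, markers in columns. Row
#'   names are line identifiers, column names marker identifiers (both
#'   required and unique).
#' @param chrom per-marker chromosome label (recycled if length 1).
#' @param pos per-marker 1-based physical position.
#' @param ref,alt per-marker reference / alternate allele symbols.
#' @param strict if `TRUE` (default), dosages must be exactly 0/1/2/`NA`;
#'   set `FALSE` for imputed matrices with fractional dosages.
#' @return an object of class `GenotypeMatrix` with elements `dosages` and
#'   `map` (data frame: `marker_id`, `chrom`, `pos`, `ref`, `alt`).
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), c("m1", "m2")))
#' g <- genotype_matrix(d, chrom = "1", pos = c(100, 200))
#' n_markers(g)
#' @export
genotype_matrix <- function(dosages, chrom = "1", pos = seq_len(ncol(dosages)),
                            ref = "A", alt = "T", strict = TRUE) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("'dosages' must be a numeric matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("'dosages' must have row names (lines) and column names (markers)")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate line ids")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker ids")
  vals <- dosages[!is.na(dosages)]
  if (strict && length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (!strict && length(vals) && (any(vals < 0) || any(vals > 2)))
    stop("dosages must lie in [0, 2]")
  m <- ncol(dosages)
  map <- data.frame(
    marker_id = colnames(dosages),
    chrom = as.character(rep_len(chrom, m)),
    pos = as.integer(rep_len(pos, m)),
    ref = as.character(rep_len(ref, m)),
    alt = as.character(rep_len(alt, m)),
    stringsAsFactors = FALSE
  )
  structure(list(dosages = dosages, map = map), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d lines x %d markers (%d chromosome%s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chrom)),
              if (length(unique(x$map$chrom)) == 1) "" else "s",
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `GenotypeMatrix`.
#' @export
n_lines <- function(g) nrow(g$dosages)

#' @rdname genotype_matrix
#' @export
n_markers <- function(g) ncol(g$dosages)

#' @rdname genotype_matrix
#' @export
line_ids <- function(g) rownames(g$dosages)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(g) colnames(g$dosages)

#' Subset a genotype matrix by lines and/or markers
#'
#' @param x a `GenotypeMatrix`.
#' @param i line index (integer, logical or character).
#' @param j marker index (integer, logical or character).
#' @param ... ignored.
#' @export
`[.GenotypeMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  jj <- match(colnames(d), x$map$marker_id)
  structure(list(dosages = d, map = x$map[jj, , drop = FALSE]),
            class = "GenotypeMatrix")
}

# coerce GenotypeMatrix or plain matrix to a dosage matrix
as_dosage_matrix <- function(g) {
  if (inherits(g, "GenotypeMatrix")) return(g$dosages)
  if (is.matrix(g) && is.numeric(g)) return(g)
  stop("expected a GenotypeMatrix or numeric matrix")
}

#' Per-marker minor allele frequency
#'
#' Computed from non-missing calls only; invariant under allele relabeling
#' (dosage x -> 2 - x).
#'
#' @param g a `GenotypeMatrix` or dosage matrix.
#' @return named numeric vector of frequencies in `[0, 0.5]` (`NaN` for
#'   markers with no non-missing calls).
#' @export
marker_maf <- function(g) {
  d <- as_dosage_matrix(g)
  p <- colMeans(d, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-marker missing-call rate
#'
#' @inheritParams marker_maf
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
marker_missing_rate <- function(g) {
  d <- as_dosage_matrix(g)
  colMeans(is.na(d))
}

#' Sort markers by chromosome and position
#'
#' Pruning and other position-aware operations require markers ordered by
#' `(chrom, pos)` within the matrix.
#'
#' @param g a `GenotypeMatrix`.
#' @return the reordered `GenotypeMatrix`.
#' @export
sort_markers <- function(g) {
  o <- order(g$map$chrom, g$map$pos)
  g[, o]
}

#' Construct a line panel with subgroup labels
#'
#' @param line_id character vector of unique line identifiers.
#' @param subgroup per-line subgroup label; vocabulary is closed to
#'   `NSS`, `SS`, `TST`, `MIXED`.
#' @return a data frame of class `LinePanel` with columns `line_id`,
#'   `subgroup`.
#' @export
line_panel <- function(line_id, subgroup) {
  if (anyDuplicated(line_id)) stop("duplicate line ids")
  if (length(subgroup) != length(line_id))
    stop("'subgroup' must match 'line_id' in length")
  subgroup <- as.character(subgroup)
  bad <- setdiff(unique(subgroup), subgroup_levels())
  if (length(bad))
    stop("unknown subgroup label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(subgroup_levels(), collapse = ", "), ")")
  structure(data.frame(line_id = as.character(line_id), subgroup = subgroup,
                       stringsAsFactors = FALSE),
            class = c("LinePanel", "data.frame"))
}
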