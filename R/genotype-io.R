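#' Read a genotype panel from VCF or a dosage table
#'
#' Two formats are supported. `vcf`: VCF v4.x with biallelic SNP records;
#' dosages are the count of the ALT allele taken from the GT field
#' (`./.` becomes missing); multiallelic records are skipped with a warning
#' and the skip count is attached as attribute `n_skipped`. `dosage_table`:
#' a tab-separated table whose header row holds marker ids, first column
#' `line_id`, cells 0/1/2/NA, with a companion marker-map file
#' (`marker_id`, `chrom`, `pos`, `ref`, `alt`).
#'
#' Marker order is the file order in both formats.
#'
#' @param path path to the VCF or dosage table.
#' @param format `"vcf"` or `"dosage_table"`.
#' @param map_path path to the marker map (dosage_table format only; if
#'   omitted, `<path>.map` is tried, and a default map is synthesised when
#'   neither exists).
#' @return a [genotype_matrix()].
#' @seealso [write_dosage_table()]
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_table"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_dosage(path, map_path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    warning(sprintf("skipped %d non-biallelic-SNP record(s)", n_skipped))
  if (!any(biallelic)) stop("zero biallelic SNP markers in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  if (anyDuplicated(ids)) stop("duplicate marker ids in ", path)
  if (anyDuplicated(colnames(gt))) stop("duplicate line ids in ", path)
  # count ALT alleles in the GT string; any missing allele -> NA
  dos <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al != "0")
  })
  dos <- t(dos) # lines x markers
  colnames(dos) <- ids
  g <- genotype_matrix(dos, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = ref[biallelic], alt = alt[biallelic])
  attr(g, "n_skipped") <- n_skipped
  g
}

read_genotypes_dosage <- function(path, map_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("zero markers in ", path)
  if (names(tab)[1] != "line_id")
    stop("dosage table must have 'line_id' as its first column")
  if (anyDuplicated(tab$line_id)) stop("duplicate line ids in ", path)
  if (anyDuplicated(names(tab)[-1])) stop("duplicate marker ids in ", path)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- tab$line_id
  if (is.null(map_path) && file.exists(paste0(path, ".map")))
    map_path <- paste0(path, ".map")
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             colClasses = "character")
    map$pos <- as.integer(map$pos)
    idx <- match(colnames(dos), map$marker_id)
    if (anyNA(idx)) stop("marker map is missing markers present in ", path)
    genotype_matrix(dos, chrom = map$chrom[idx], pos = map$pos[idx],
                    ref = map$ref[idx], alt = map$alt[idx],
                    strict = FALSE)
  } else {
    genotype_matrix(dos, strict = FALSE)
  }
}

#' Write a genotype panel as a dosage table plus marker map
#'
#' The inverse of `read_genotypes(format = "dosage_table")`; a
#' write-then-read round trip reproduces the matrix exactly.
#'
#' @param g a `GenotypeMatrix`.
#' @param path output path for the tab-separated dosage table.
#' @param map_path output path for the marker map (default `<path>.map`).
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(g, path, map_path = paste0(path, ".map")) {
  d <- g$dosages
  tab <- data.frame(line_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
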