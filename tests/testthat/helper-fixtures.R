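# fixtures and independent oracles shared across test files

# random raw genotype matrix (no structure), optionally with missing calls
toy_genotype <- function(n = 6, m = 10, miss = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("L%02d", 1:n), sprintf("m%02d", 1:m)))
  d <- d * 1.0
  if (miss > 0) d[sample(length(d), miss)] <- NA_real_
  genotype_matrix(d, chrom = "1", pos = seq_len(m) * 100)
}

# small structured panel + polygenic trait, memoised per options string
sim_panel_cache <- new.env(parent = emptyenv())
small_sim <- function(n_markers = 400, sizes = c(NSS = 60, SS = 20,
                                                 TST = 80, MIXED = 40),
                      h2 = 0.41, seed = 11, architecture = "polygenic",
                      ...) {
  key <- paste(n_markers, paste(sizes, collapse = ","), h2, seed,
               architecture, paste(c(...), collapse = ","), sep = "_")
  if (!is.null(sim_panel_cache[[key]])) return(sim_panel_cache[[key]])
  cfg <- simulation_config(subgroup_sizes = sizes, n_markers = n_markers,
                           h2_target = h2, seed = seed, ...)
  gsim <- simulate_structured_genotypes(cfg)
  tr <- simulate_trait(gsim$genotype, gsim$panel, cfg,
                       architecture = architecture)
  out <- list(genotype = gsim$genotype, panel = gsim$panel, cfg = cfg,
              phenotypes = tr$phenotypes, truth = tr$truth)
  sim_panel_cache[[key]] <- out
  out
}

# minimal VCF fixture; optionally includes one triallelic record
write_test_vcf <- function(path, triallelic = FALSE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", "L3", sep = "\t"))
  rec <- c(
    paste("1", "100", "s1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "s2", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "./.", "0/1", sep = "\t"))
  if (triallelic)
    rec <- c(rec, paste("1", "300", "s3", "T", "A,G", ".", "PASS", ".",
                        "GT", "0/0", "0/1", "1/1", sep = "\t"))
  writeLines(c(header, rec), path)
  path
}

# independent gBLUP oracle: kinship mixed model solved by determinant-based
# REML profiling and the mixed-model equations, no spectral shortcut
gblup_oracle <- function(d, y) {
  Z <- scale(d, scale = FALSE)
  K <- tcrossprod(Z) / ncol(Z)
  n <- nrow(K)
  prof <- function(loglam) {
    lam <- exp(loglam)
    H <- K + lam * diag(n)
    Hi <- solve(H)
    mu <- sum(Hi %*% y) / sum(Hi)
    r <- y - mu
    q <- as.numeric(crossprod(r, Hi %*% r))
    as.numeric(determinant(H, logarithm = TRUE)$modulus) +
      log(sum(Hi)) + (n - 1) * log(q)
  }
  opt <- stats::optimize(prof, c(-12, 12), tol = 1e-8)
  lam <- exp(opt$minimum)
  H <- K + lam * diag(n)
  Hi <- solve(H)
  mu <- sum(Hi %*% y) / sum(Hi)
  gebv <- mu + as.vector(K %*% (Hi %*% (y - mu)))
  list(mu = mu, gebv = stats::setNames(gebv, rownames(d)), lambda = lam)
}

# exhaustive greedy LD pruning without windows: recompute the full r2
# matrix after each removal; same tie-break rule as the package
greedy_prune_oracle <- function(d, pos, thr) {
  keep <- seq_len(ncol(d))
  repeat {
    r2 <- suppressWarnings(stats::cor(d[, keep, drop = FALSE]))^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 0
    if (length(keep) < 2 || max(r2) <= thr) break
    off <- unique(as.vector(which(r2 > thr, arr.ind = TRUE)))
    mr <- rowMeans(r2[off, , drop = FALSE])
    worst <- off[order(-mr, -pos[keep][off])][1]
    keep <- keep[-worst]
  }
  keep
}
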