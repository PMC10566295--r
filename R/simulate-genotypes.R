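#' Simulation configuration for structured maize-like panels
#'
#' Collects every knob of the synthetic generator. Defaults emulate the
#' association panel the package targets: 438 inbred lines in four
#' subgroups (121 NSS, 30 SS, 186 TST, 101 MIXED), block-structured
#' linkage disequilibrium, a trait with broad-sense heritability 0.41
#' measured in 3 environments x 2 replicates, and moderate
#' genotype-by-environment variance.
#'
#' @param subgroup_sizes named integer vector of lines per subgroup; names
#'   from `NSS`, `SS`, `TST`, `MIXED`.
#' @param n_markers total marker count.
#' @param n_chrom number of chromosomes (markers split evenly; default 10,
#'   the maize karyotype).
#' @param fst Balding-Nichols divergence of each pure subgroup from the
#'   ancestral pool, in (0,1). Scalar or named per-subgroup
#'   (`NSS`, `SS`, `TST`; `MIXED` is an admixture, not diverged itself).
#' @param block_len markers per LD block.
#' @param within_block_r2 target squared allele correlation between markers
#'   of the same block, in `[0, 1]`.
#' @param between_block_r2 target squared correlation between markers of
#'   adjacent blocks (decays geometrically with block distance).
#' @param inbreeding probability that a line's second haplotype is a copy
#'   of its first (inbred-line autozygosity; default 0.95).
#' @param n_qtl number of causal markers; `NULL` lets
#'   [simulate_trait()] pick an architecture-dependent default.
#' @param h2_target broad-sense heritability the phenotype is scaled to,
#'   on the multi-environment design basis.
#' @param n_env,n_rep environments and replicates per environment.
#' @param gxe_var_frac genotype-by-environment variance as a fraction of
#'   genotypic variance.
#' @param missing_rate fraction of genotype calls set to missing (default
#'   0, i.e. a clean matrix).
#' @param seed integer seed; fixing it makes every simulator output
#'   reproducible.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(subgroup_sizes = c(NSS = 121, SS = 30,
                                                 TST = 186, MIXED = 101),
                              n_markers = 5000, n_chrom = 10,
                              fst = 0.1, block_len = 5,
                              within_block_r2 = 0.8,
                              between_block_r2 = 0.04,
                              inbreeding = 0.95,
                              n_qtl = NULL, h2_target = 0.41,
                              n_env = 3, n_rep = 2,
                              gxe_var_frac = 0.3,
                              missing_rate = 0, seed = 1) {
  if (is.null(names(subgroup_sizes)) ||
      !all(names(subgroup_sizes) %in% subgroup_levels()))
    stop("subgroup_sizes must be named with labels from ",
         paste(subgroup_levels(), collapse = ", "))
  if (any(subgroup_sizes <= 0)) stop("subgroup sizes must be positive")
  if (any(fst <= 0) || any(fst >= 1)) stop("fst must lie in (0, 1)")
  if (block_len < 1 || block_len > n_markers)
    stop("block_len must lie in [1, n_markers]")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must lie in [0, 1]")
  if (within_block_r2 < 0 || within_block_r2 > 1)
    stop("within_block_r2 must lie in [0, 1]")
  if (!is.null(n_qtl) && n_qtl > n_markers) stop("n_qtl exceeds n_markers")
  structure(list(subgroup_sizes = subgroup_sizes, n_markers = n_markers,
                 n_chrom = n_chrom, fst = fst, block_len = block_len,
                 within_block_r2 = within_block_r2,
                 between_block_r2 = between_block_r2,
                 inbreeding = inbreeding, n_qtl = n_qtl,
                 h2_target = h2_target, n_env = n_env, n_rep = n_rep,
                 gxe_var_frac = gxe_var_frac, missing_rate = missing_rate,
                 seed = seed),
            class = "SimulationConfig")
}

#' Simulate an Fst-structured inbred genotype panel with block LD
#'
#' Pure subgroups (NSS, SS, TST) get block-level allele frequencies drawn
#' from a Balding-Nichols model around a shared ancestral frequency
#' (uniform on `[0.05, 0.95]`); the MIXED subgroup draws, per line, a
#' random convex mixture of the three pure frequency vectors. Haplotypes
#' are built by a latent-uniform copying scheme: all markers of a block
#' share the block frequency and copy a block-level latent uniform with
#' probability `within_block_r2^(1/4)`, giving within-block allele
#' r-squared equal to `within_block_r2` in expectation (exactly 1 when the
#' target is 1); block latents follow a Markov copy chain along each
#' chromosome so inter-block LD decays geometrically. Lines are inbred:
#' with probability `inbreeding` the second haplotype is a copy of the
#' first.
#'
#' @param cfg a [simulation_config()].
#' @return a list with `genotype` (a `GenotypeMatrix`), `panel` (a
#'   [line_panel()]) and `truth` (partial `SimTruth`: `ancestral_freqs`
#'   and per-subgroup `subgroup_freqs`).
#' @export
simulate_structured_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "genotypes"))
  m <- cfg$n_markers
  n_blocks <- ceiling(m / cfg$block_len)
  block_of <- rep(seq_len(n_blocks), each = cfg$block_len)[seq_len(m)]
  # split blocks (never markers of one block) across chromosomes
  chrom_of_block <- sort(rep_len(seq_len(cfg$n_chrom), n_blocks))
  chrom <- chrom_of_block[block_of]
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    seq_along(ix) * 1000L), use.names = FALSE)

  pure <- c("NSS", "SS", "TST")
  fst <- if (length(cfg$fst) == 1) stats::setNames(rep(cfg$fst, 3), pure) else cfg$fst
  anc_block <- stats::runif(n_blocks, 0.05, 0.95)
  # Balding-Nichols divergence at block level, one frequency per block
  freq_block <- sapply(pure, function(s) {
    f <- fst[[s]]
    stats::rbeta(n_blocks, anc_block * (1 - f) / f,
                 (1 - anc_block) * (1 - f) / f)
  })

  # two markers both copy their block latent with prob c^2, so the
  # within-block allele correlation is c^2 and r2 = c^4; between adjacent
  # blocks r2 ~ (c^2 * d * kappa)^2 with kappa the frequency-mismatch
  # attenuation (~0.55 for Balding-Nichols draws)
  c_within <- cfg$within_block_r2^(1 / 4)
  d_between <- if (cfg$between_block_r2 <= 0 || c_within == 0) 0 else
    min(0.95, sqrt(cfg$between_block_r2) / (c_within^2 * 0.55))

  sizes <- cfg$subgroup_sizes
  n <- sum(sizes)
  dos <- matrix(0, n, m)
  subgroup <- rep(names(sizes), sizes)
  rownames(dos) <- sprintf("L%03d_%s", seq_len(n), subgroup)
  colnames(dos) <- sprintf("snp%05d", seq_len(m))

  draw_hap <- function(pb) {
    # pb: per-block allele frequency for this line's source population
    u_block <- numeric(n_blocks)
    for (ch in unique(chrom_of_block)) {
      ix <- which(chrom_of_block == ch)
      fresh <- stats::runif(length(ix)) >= d_between
      fresh[1] <- TRUE
      grp <- cumsum(fresh)
      u_block[ix] <- stats::runif(max(grp))[grp]
    }
    copy <- stats::runif(m) < c_within
    u <- ifelse(copy, u_block[block_of], stats::runif(m))
    as.numeric(u < pb[block_of])
  }

  for (i in seq_len(n)) {
    s <- subgroup[i]
    pb <- if (s == "MIXED") {
      w <- stats::rgamma(3, 1)
      w <- w / sum(w)
      as.vector(freq_block %*% w)
    } else freq_block[, s]
    h1 <- draw_hap(pb)
    h2 <- if (stats::runif(1) < cfg$inbreeding) h1 else draw_hap(pb)
    dos[i, ] <- h1 + h2
  }

  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < cfg$missing_rate
    dos[miss] <- NA_real_
  }

  g <- genotype_matrix(dos, chrom = as.character(chrom), pos = pos)
  panel <- line_panel(rownames(dos), subgroup)
  truth <- structure(list(
    ancestral_freqs = anc_block[block_of],
    subgroup_freqs = freq_block[block_of, , drop = FALSE]
  ), class = "SimTruth")
  list(genotype = g, panel = panel, truth = truth)
}

#' Hudson-type Fst between two subgroups of a panel
#'
#' Ratio-of-averages Hudson estimator with sample-size correction, from
#' realized allele frequencies; used to verify that the generator attains
#' its divergence target.
#'
#' @param g a `GenotypeMatrix` (no missing calls assumed relevant;
#'   frequencies use non-missing calls).
#' @param panel a [line_panel()].
#' @param s1,s2 subgroup labels to compare.
#' @return a single Fst value.
#' @export
hudson_fst <- function(g, panel, s1, s2) {
  d <- as_dosage_matrix(g)
  i1 <- panel$line_id[panel$subgroup == s1]
  i2 <- panel$line_id[panel$subgroup == s2]
  if (length(i1) < 2 || length(i2) < 2) stop("need >= 2 lines per subgroup")
  p1 <- colMeans(d[i1, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(d[i2, , drop = FALSE], na.rm = TRUE) / 2
  n1 <- 2 * length(i1); n2 <- 2 * length(i2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
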