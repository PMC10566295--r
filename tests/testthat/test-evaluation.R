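test_that("prediction ability reduces to Pearson correlation with its guards", {
  set.seed(1)
  obs <- stats::setNames(rnorm(50), paste0("L", 1:50))
  expect_equal(prediction_ability(obs, obs), 1)
  expect_equal(prediction_ability(2 + 3 * obs, obs), 1) # affine invariance
  shuffled <- stats::setNames(sample(obs), names(obs))
  expect_lt(abs(prediction_ability(shuffled, obs)), 0.45)
  expect_error(prediction_ability(obs[1:2], obs[1:2]), "3 overlapping")
  expect_error(prediction_ability(stats::setNames(rep(1, 50), names(obs)),
                                  obs), "constant")
})

test_that("cv_scheme validates scope and fraction combinations", {
  expect_error(cv_scheme(0), "\\(0, 1\\)")
  expect_error(cv_scheme(0.2, scope = "within_subgroup"), "requires")
  expect_error(cv_scheme(0.2, focal_subgroup = "SS"), "forbids")
  expect_error(cv_scheme(0.2, scope = "across_subgroup",
                         focal_subgroup = "XX"), "unknown")
  sc <- cv_scheme(0.3, n_repeats = 10, seed = 5)
  expect_s3_class(sc, "CVScheme")
})

test_that("run_cv is deterministic and invariant to line order", {
  sim <- small_sim(n_markers = 200, sizes = c(NSS = 30, SS = 10, TST = 40,
                                              MIXED = 20), seed = 41)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  sc <- cv_scheme(0.3, n_repeats = 5, seed = 7)
  r1 <- run_cv(d, y, "rrblup", sc)
  r2 <- run_cv(d, y, "rrblup", sc)
  expect_identical(r1$abilities, r2$abilities)
  expect_equal(length(r1$abilities), 5L)
  expect_true(all(abs(r1$abilities) <= 1))
  # permuting line order leaves the mean ability distribution identical
  perm <- sample(nrow(d))
  r3 <- run_cv(d[perm, ], y[perm], "rrblup", sc)
  # identical partitions; tiny float noise from reordered accumulation
  expect_equal(r3$mean_ability, r1$mean_ability, tolerance = 1e-6)
})

test_that("per-repeat partitions are disjoint and exhaustive", {
  ids <- sample(sprintf("L%02d", 1:40)) # deliberately unsorted frame
  sc <- cv_scheme(0.25, n_repeats = 8, seed = 3)
  n_test <- round(0.25 * length(ids))
  pool <- sort(ids)
  for (r in 1:8) {
    s <- huskGS:::derive_seed(sc$seed, "whole", "rrblup", r)
    set.seed(s)
    test <- pool[sample.int(length(ids), n_test)]
    train <- setdiff(ids, test)
    expect_length(intersect(train, test), 0)
    expect_setequal(c(train, test), ids)
  }
})

test_that("subgroup CV respects the within/across sampling frames", {
  sim <- small_sim(n_markers = 150, sizes = c(NSS = 40, SS = 15, TST = 50,
                                              MIXED = 25), seed = 43)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  focal_ids <- sim$panel$line_id[sim$panel$subgroup == "TST"]

  sc_w <- cv_scheme(0.4, n_repeats = 3, scope = "within_subgroup",
                    focal_subgroup = "TST", seed = 11)
  rw <- run_subgroup_cv(d, y, sim$panel, "rrblup", sc_w)
  expect_length(rw$abilities, 3L)

  # replicate the partition of repeat 1 and audit it
  s <- huskGS:::derive_seed(sc_w$seed, "subgroup", "within_subgroup",
                            "TST", "rrblup", 1)
  set.seed(s)
  pool <- sort(intersect(rownames(d), focal_ids))
  n_train <- round(0.6 * length(pool))
  train <- pool[sample.int(length(pool), n_train)]
  test_within <- setdiff(pool, train)
  expect_setequal(union(train, test_within), pool)
  expect_length(intersect(train, test_within), 0)

  # across scope: testing set = focal remainder + all non-focal lines
  sc_a <- cv_scheme(0.4, n_repeats = 3, scope = "across_subgroup",
                    focal_subgroup = "TST", seed = 11)
  ra <- run_subgroup_cv(d, y, sim$panel, "rrblup", sc_a)
  expect_length(ra$abilities, 3L)
  n_expected_test <- (length(pool) - n_train) + (nrow(d) - length(pool))
  s2 <- huskGS:::derive_seed(sc_a$seed, "subgroup", "across_subgroup",
                             "TST", "rrblup", 1)
  set.seed(s2)
  train2 <- pool[sample.int(length(pool), n_train)]
  test_across <- setdiff(rownames(d), train2)
  expect_length(test_across, n_expected_test)

  expect_error(run_subgroup_cv(d, y, sim$panel, "rrblup",
                               cv_scheme(0.4, scope = "within_subgroup",
                                         focal_subgroup = "SS", seed = 1)),
               NA) # SS has 15 lines, still allowed
})

test_that("null traits give near-zero mean ability", {
  sim <- small_sim(n_markers = 150, sizes = c(NSS = 40, SS = 15, TST = 60,
                                              MIXED = 25), h2 = 0, seed = 47)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  res <- run_cv(d, y, "rrblup", cv_scheme(0.2, n_repeats = 20, seed = 5))
  expect_lt(abs(res$mean_ability), 0.15)
})

test_that("factorial_run builds the full cross-product deterministically", {
  sim <- small_sim(n_markers = 150, sizes = c(NSS = 30, SS = 12, TST = 40,
                                              MIXED = 18), seed = 51)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  g <- sim$genotype[names(y), ]
  sc <- cv_scheme(0.3, n_repeats = 2, seed = 13)
  tab <- factorial_run(list(chip = g), y, models = c("rrblup", "BRR"),
                       densities = c(0.2, 1.0), schemes = list(sc),
                       model_args = list(iters = 200, burnin = 50))
  # 1 set x 2 densities x 2 models x 1 scheme x 2 repeats = 8 rows
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$model), c("rrblup", "BRR"))
  expect_setequal(unique(tab$density_r2), c(0.2, 1.0))
  tab2 <- factorial_run(list(chip = g), y, models = c("rrblup", "BRR"),
                        densities = c(0.2, 1.0), schemes = list(sc),
                        model_args = list(iters = 200, burnin = 50))
  expect_identical(tab$ability, tab2$ability)

  # a failing cell (tiny subgroup) is recorded, not fatal
  bad <- cv_scheme(0.95, n_repeats = 2, scope = "within_subgroup",
                   focal_subgroup = "SS", seed = 1)
  tab3 <- factorial_run(list(chip = g), y, models = "rrblup",
                        densities = 1.0,
                        schemes = list(sc, bad), panel = sim$panel)
  expect_equal(length(attr(tab3, "failed")), 1L)
  expect_equal(nrow(tab3), 2L)
})

test_that("more repeats shrink the standard error of the mean ability", {
  sim <- small_sim(n_markers = 150, sizes = c(NSS = 30, SS = 12, TST = 40,
                                              MIXED = 18), seed = 53)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  r <- run_cv(d, y, "rrblup", cv_scheme(0.3, n_repeats = 40, seed = 21))
  se20 <- stats::sd(r$abilities[1:20]) / sqrt(20)
  se40 <- stats::sd(r$abilities) / sqrt(40)
  expect_lt(se40, se20 * 1.2) # ~ sqrt(2) shrinkage with noise allowance
})

test_that("duncan grouping separates shifted groups and matches a t-test", {
  set.seed(9)
  v <- c(rnorm(100, 0), rnorm(100, 5))
  gc <- duncan_grouping(v, rep(c("A", "B"), each = 100))
  expect_true(groups_differ(gc, "A", "B"))
  expect_equal(gc$groups$letters, c("a", "b"))

  # single pair: decision agrees with a pooled two-sample t-test
  agree <- replicate(100, {
    v <- rnorm(60, mean = rep(c(0, stats::runif(1, 0, 1)), each = 30))
    grp <- rep(c("A", "B"), each = 30)
    gc <- duncan_grouping(v, grp)
    tt <- stats::t.test(v[grp == "A"], v[grp == "B"],
                        var.equal = TRUE)$p.value < 0.05
    groups_differ(gc, "A", "B") == tt
  })
  expect_true(all(agree))

  # letters invariant: groups sharing a letter are never declared
  # different by the underlying ranges
  set.seed(10)
  v <- rnorm(300, mean = rep(c(0, 0.1, 0.5), each = 100))
  gc3 <- duncan_grouping(v, rep(c("A", "B", "C"), each = 100))
  expect_true(all(nchar(gc3$groups$letters) >= 1))
  expect_error(duncan_grouping(rep(1, 40), rep(c("A", "B"), each = 20)),
               "zero pooled")
  expect_error(duncan_grouping(rnorm(10), rep("A", 10)), "at least 2")
})
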