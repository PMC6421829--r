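test_that("Gower centering satisfies the Huygens identity and centering", {
  D0 <- matrix(0, 4, 4)
  G0 <- gower_center(D0)
  expect_equal(unclass(G0), matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(attr(G0, "ss_total"), 0)

  pts <- c(0, 3, 4)
  G <- gower_center(as.matrix(dist(pts)))
  expect_equal(attr(G, "ss_total"), sum((pts - mean(pts))^2), tolerance = 1e-12)
  expect_equal(attr(G, "ss_total"), 26 / 3, tolerance = 1e-12)
  expect_equal(unname(rowSums(G)), rep(0, 3), tolerance = 1e-12)
})

test_that("pseudo-F on Euclidean distances reproduces classical ANOVA", {
  y <- c(1, 2, 3, 10, 11, 12)
  g <- factor(rep(c("a", "b"), each = 3))
  res <- pseudo_f(gower_center(as.matrix(dist(y))), g)
  expect_equal(res$F, 121.5, tolerance = 1e-9)
  expect_equal(res$df_model, 1L); expect_equal(res$df_resid, 4L)
  expect_equal(res$R2 + res$ss_resid / res$ss_total, 1, tolerance = 1e-12)

  # no-signal limit: covariate orthogonal to the generating coordinate
  xo <- c(1, -1, 1, -1, 1, -1)
  res0 <- pseudo_f(gower_center(as.matrix(dist(c(1, 1, 2, 2, 3, 3)))), xo)
  expect_lt(res0$F, 1e-10)

  expect_error(pseudo_f(gower_center(as.matrix(dist(y))), rep(1, 6)), "constant")
})

test_that("pseudo-F matches the raw-coordinate sums-of-squares oracle", {
  set.seed(42)
  for (k in 1:50) {
    n <- sample(5:9, 1); p <- sample(2:5, 1)
    Y <- matrix(rnorm(n * p), n)
    x <- if (k %% 2) rnorm(n) else factor(sample(letters[1:2], n, replace = TRUE))
    if (is.factor(x) && length(unique(x)) < 2) x <- factor(rep(letters[1:2], length.out = n))
    res <- pseudo_f(gower_center(as.matrix(dist(Y))), x)
    oracle <- ssq_pseudo_f(Y, x)
    expect_equal(res$F, oracle$F, tolerance = 1e-9)
    expect_equal(res$R2, oracle$R2, tolerance = 1e-9)
  }
})

test_that("permanova_single agrees with vegan::adonis2 on the statistic", {
  set.seed(8)
  m <- matrix(rpois(9 * 40, 4), 9)
  x <- rnorm(9)
  D <- as.matrix(vegan::vegdist(m, "bray"))
  res <- permanova_single(D, x, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(D ~ x, permutations = 99)
  expect_equal(res$F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
})

test_that("permutation p at n = 4 matches exhaustive enumeration", {
  set.seed(31)
  for (k in 1:5) {
    D <- as.matrix(dist(matrix(rnorm(8), 4)))
    x <- rnorm(4)
    exact <- permanova_enum_p(D, x)
    res <- permanova_single(D, x, permutations = all_perms(4))
    expect_equal(res$p, exact, tolerance = 1e-12)
  }
})

test_that("p is bounded below, invariant to relabeling, and honest in extremes", {
  set.seed(4)
  m <- matrix(rpois(6 * 30, 5), 6, dimnames = list(paste0("s", 1:6), NULL))
  x <- rnorm(6)
  D <- as.matrix(vegan::vegdist(m, "bray"))
  res <- permanova_single(D, x, n_perm = 49, seed = 2)
  expect_gte(res$p, 1 / 50)
  expect_lte(res$p, 1)

  # joint relabeling of D and x leaves everything unchanged
  perm <- c(3, 1, 6, 4, 2, 5)
  res2 <- permanova_single(D[perm, perm], x[perm], n_perm = 49, seed = 2)
  expect_equal(res2$F, res$F, tolerance = 1e-12)
  expect_equal(res2$R2, res$R2, tolerance = 1e-12)

  # perfectly separated two-cluster Euclidean data reach the floor 1/(1+K):
  # full enumeration of the 720 relabelings of this asymmetric configuration
  # shows the identity is the unique maximiser of F
  y <- c(0, 0.1, 0.25, 100, 100.4, 101)
  x6 <- c(1, 2.2, 2.9, 10.5, 11.1, 13)
  G6 <- gower_center(as.matrix(dist(y)))
  fs <- apply(all_perms(6), 1, function(p) pseudo_f(G6, x6[p])$F)
  expect_equal(sum(fs >= fs[1] - sqrt(.Machine$double.eps) * fs[1]), 1)
  sep <- permanova_single(as.matrix(dist(y)), x6, n_perm = 99, seed = 5)
  expect_equal(sep$p, 1 / 100, tolerance = 1e-12)
})

test_that("one rarefaction round reproduces permanova_single exactly", {
  ds <- simulate_dataset(synthetic_config(seed = 21, n_otus = 60))
  dna <- subset_fraction(ds$counts, "DNA")
  x <- align_env(ds$env, dna)$chlorophyll_sum
  depth <- min(sample_depths(dna))
  rr <- permanova_rarefied(dna, x, "bray_weighted", depth = depth,
                           rarefactions = 1, n_perm = 99, seed = 7)
  rt <- rarefy_counts(dna, depth, seed = derive_seed(7, 1))
  single <- permanova_single(distance_matrix(rt, "bray_weighted"), x,
                             n_perm = 99, seed = derive_seed(7, 2))
  expect_equal(rr$F, single$F, tolerance = 1e-12)
  expect_equal(rr$R2, single$R2, tolerance = 1e-12)
  expect_equal(rr$p, single$p, tolerance = 1e-12)
})

test_that("pooled repeated-rarefaction p never hits zero and tracks effect size", {
  ds0 <- simulate_dataset(synthetic_config(seed = 33, n_otus = 80,
                                           effect_size_chl = 0))
  ds1 <- simulate_dataset(synthetic_config(seed = 33, n_otus = 80,
                                           effect_size_chl = 2))
  run <- function(ds) {
    dna <- subset_fraction(ds$counts, "DNA")
    permanova_rarefied(dna, align_env(ds$env, dna)$chlorophyll_sum,
                       "bray_weighted", depth = min(sample_depths(dna)),
                       rarefactions = 10, n_perm = 49, seed = 2)
  }
  p0 <- run(ds0); p1 <- run(ds1)
  expect_gte(p1$p, 1 / (1 + 10 * 49))
  expect_lt(p1$p, p0$p)          # planted signal beats the null dataset
  expect_equal(nrow(p1$trace), 10)
  expect_s3_class(p1, "rr_permanova")
})

test_that("reused permutations across rarefactions are supported and deterministic", {
  ds <- simulate_dataset(synthetic_config(seed = 10, n_otus = 50))
  dna <- subset_fraction(ds$counts, "DNA")
  x <- align_env(ds$env, dna)$chlorophyll_sum
  depth <- min(sample_depths(dna))
  a <- permanova_rarefied(dna, x, "bray_weighted", depth = depth,
                          rarefactions = 5, n_perm = 29, seed = 3,
                          reuse_permutations = TRUE)
  b <- permanova_rarefied(dna, x, "bray_weighted", depth = depth,
                          rarefactions = 5, n_perm = 29, seed = 3,
                          reuse_permutations = TRUE)
  expect_identical(a$p, b$p)
  expect_identical(a$trace$F, b$trace$F)
})
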