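test_that("rarefaction returns the sample unchanged at full depth, errors below it", {
  ct <- toy_counts(rbind(s1 = c(a = 3, b = 7)))
  expect_identical(unclass(rarefy_counts(ct, 10, seed = 1)), unclass(ct))
  expect_error(rarefy_counts(ct, 11), "s1")
  r <- rarefy_counts(toy_counts(rbind(s1 = c(a = 30, b = 70),
                                      s2 = c(a = 50, b = 60))), 25, seed = 2)
  expect_true(all(rowSums(unclass(r)) == 25))
  expect_identical(colnames(r), c("a", "b"))
})

test_that("rarefied counts follow the hypergeometric law (mean and variance)", {
  # counts (10, 10) rarefied to 10: taxon-1 count ~ Hypergeom(N=20, K=10, n=10)
  ct <- toy_counts(rbind(s1 = c(a = 10, b = 10)))
  reps <- 5000
  draws <- vapply(seq_len(reps),
                  function(i) unclass(rarefy_counts(ct, 10, seed = i))[1, 1],
                  numeric(1))
  mu <- 10 * 10 / 20
  v <- 10 * (10 / 20) * (10 / 20) * (20 - 10) / (20 - 1)
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / reps))
  expect_lt(abs(var(draws) - v), 0.15)
})

test_that("richness and Shannon match their definitions", {
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(1, 0, 2)), 2)
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(7, 7, 7, 7)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  # permutation invariance and zero-taxon padding
  x <- c(4, 1, 9, 2)
  expect_equal(shannon_index(x), shannon_index(rev(x)))
  expect_equal(shannon_index(x), shannon_index(c(x, 0, 0)))
})

test_that("Faith's PD matches hand traversals and picante, and is monotone", {
  tr <- toy_tree()  # ((A:1,B:2):3,C:4);
  expect_equal(faith_pd(c(A = 1, B = 0, C = 0), tr), 4)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 0), tr), 6)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1), tr), 10)
  expect_error(faith_pd(c(A = 1, Z = 1), tr), "Z")

  # cross-check against picante's root-inclusive pd on random communities
  set.seed(77)
  for (k in 1:5) {
    nt <- sample(10:30, 1)
    tt <- ape::rtree(nt); tt$tip.label <- paste0("t", seq_len(nt))
    m <- matrix(rbinom(4 * nt, 3, 0.4), 4,
                dimnames = list(paste0("s", 1:4), tt$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    expect_equal(unname(faith_pd(m, tt)),
                 picante::pd(m, tt, include.root = TRUE)$PD, tolerance = 1e-12)
  }

  # monotone under taxon addition, property-style over many random cases
  set.seed(99)
  for (k in 1:500) {
    nt <- sample(5:25, 1)
    tt <- ape::rtree(nt); tt$tip.label <- paste0("t", seq_len(nt))
    pres <- rbinom(nt, 1, 0.4)
    if (!sum(pres)) pres[sample(nt, 1)] <- 1
    x <- setNames(pres, tt$tip.label)
    absent <- which(x == 0)
    if (!length(absent)) next
    y <- x; y[sample(absent, 1)] <- 1
    expect_gte(faith_pd(y, tt), faith_pd(x, tt))
  }
})

test_that("analytic rarefaction curve is exact, concave and anchored", {
  cur <- rarefaction_curve(c(2, 2), 1:4)
  expect_equal(cur$expected_richness[2], 5 / 3, tolerance = 1e-12)
  expect_equal(cur$expected_richness[1], 1)          # one read, one species
  expect_equal(cur$expected_richness[4], 2)          # full depth = S_obs
  expect_error(rarefaction_curve(c(2, 2), 5), "exceeds")

  set.seed(3)
  x <- rmultinom(1, 400, prob = rgamma(30, 0.5))[, 1]
  grid <- seq(1, 391, by = 10)        # uniform step so concavity = 2nd differences
  es <- rarefaction_curve(x, grid)$expected_richness
  expect_true(all(diff(es) >= -1e-10))               # non-decreasing
  expect_true(all(diff(diff(es)) <= 1e-8))           # concave
  # direct lchoose evaluation as an independent formula check
  n0 <- 57; N <- sum(x)
  direct <- sum(1 - exp(lchoose(N - x, n0) - lchoose(N, n0)))
  expect_equal(rarefaction_curve(x, n0)$expected_richness, direct,
               tolerance = 1e-10)
})

test_that("sample-based accumulation matches the exact combinatorial form", {
  ct <- toy_counts(rbind(s1 = c(a = 5, b = 2), s2 = c(a = 0, b = 3)))
  sa <- species_accumulation(ct)
  # taxon a only in s1 contributes 0.5 at k = 1; ubiquitous b contributes 1
  expect_equal(sa$expected_richness, c(1.5, 2), tolerance = 1e-12)
  expect_error(species_accumulation(ct, k_grid = 3), "exceeds")

  ds <- simulate_dataset(synthetic_config(seed = 4, n_otus = 60))
  dna <- subset_fraction(ds$counts, "DNA")
  sa2 <- species_accumulation(dna)
  expect_equal(sa2$expected_richness[nrow(sa2)], sum(colSums(unclass(dna)) > 0))
  T_ <- nrow(dna); t_i <- colSums(unclass(dna) > 0); t_i <- t_i[t_i > 0]
  for (k in c(1, 4)) {
    direct <- sum(1 - exp(lchoose(T_ - t_i, k) - lchoose(T_, k)))
    expect_equal(sa2$expected_richness[k], direct, tolerance = 1e-8)
  }
})

test_that("Michaelis-Menten fits recover exact curves and behave sanely", {
  x <- seq(10, 1000, by = 10)
  y <- 100 * x / (50 + x)
  f <- fit_michaelis_menten(x, y)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(100, 50), tolerance = 1e-6)
  expect_equal(predict(f, c(50, 100)), c(50, 100 * 100 / 150), tolerance = 1e-6)

  # degenerate flat curve never claims convergence
  expect_false(fit_michaelis_menten(x, rep(7, length(x)))$converged)

  # scale equivariance: x -> c*x scales e, leaves d
  f2 <- fit_michaelis_menten(3 * x, y)
  expect_equal(f2$d, f$d, tolerance = 1e-6)
  expect_equal(f2$e, 3 * f$e, tolerance = 1e-5)

  # grid-search oracle agreement on a noisy curve
  set.seed(12)
  yn <- y + rnorm(length(y))
  fn <- fit_michaelis_menten(x, yn)
  oracle <- mm_grid_oracle(x, yn)
  expect_equal(fn$d, unname(oracle["d"]), tolerance = 0.01)
  expect_equal(fn$e, unname(oracle["e"]), tolerance = 0.05)
  expect_lte(fn$rss, oracle["rss"] + 1e-8)
})

test_that("coverage is observed richness over the fitted asymptote", {
  x <- seq(20, 2000, by = 20)
  f <- fit_michaelis_menten(x, 100 * x / (50 + x))
  expect_equal(coverage_estimate(100, f), 100, tolerance = 1e-5)
  expect_equal(coverage_estimate(88.1, f), 88.1, tolerance = 1e-4)
  expect_warning(cov <- coverage_estimate(110, f), "exceeds")
  expect_gt(cov, 100)
  bad <- fit_michaelis_menten(x, rep(1, length(x)))
  expect_error(coverage_estimate(50, bad), "converge")
})

test_that("alpha_profile averages correctly and matches the analytic expectation", {
  ds <- simulate_dataset(synthetic_config(seed = 6, n_otus = 80))
  dna <- subset_fraction(ds$counts, "DNA")
  depth <- min(sample_depths(dna))

  # iterations = 1 equals a single-pass computation with the same child seed
  prof1 <- alpha_profile(dna, ds$tree, depth, iterations = 1, seed = 10)
  rt <- rarefy_counts(dna, depth, seed = derive_seed(10, 1))
  expect_equal(prof1$richness, unname(richness(unclass(rt))))
  expect_equal(prof1$shannon, unname(shannon_index(unclass(rt))))
  expect_equal(prof1$faith_pd, unname(faith_pd(unclass(rt), ds$tree)))

  # identical samples give zero between-sample variance in every index
  same <- count_table(matrix(rep(c(5L, 3L, 0L, 2L), each = 3), 3,
                             dimnames = list(paste0("s", 1:3), paste0("o", 1:4))))
  tr4 <- ape::rtree(4); tr4$tip.label <- paste0("o", 1:4)
  ps <- alpha_profile(same, tr4, depth = 10, iterations = 5, seed = 3)
  expect_equal(var(ps$richness), 0)
  expect_equal(var(ps$shannon), 0)
  expect_equal(var(ps$faith_pd), 0)

  # mean richness over iterations sits on the analytic rarefaction curve
  prof <- alpha_profile(dna[1, ], ds$tree, depth, iterations = 60, seed = 5)
  analytic <- rarefaction_curve(unclass(dna)[1, ], depth)$expected_richness
  expect_lt(abs(prof$richness[1] - analytic), 4)   # ~4 sd of the MC mean
  expect_true(all(prof$shannon <= log(prof$richness) + 1e-9))
  expect_true(prof$mm_converged[1])
  expect_true(prof$coverage[1] > 0 && prof$coverage[1] <= 110)
})
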