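test_that("Spearman test matches hand values and monotone invariance", {
  res <- spearman_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res$rho, -0.5, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  expect_equal(spearman_test(1:8, exp(1:8))$rho, 1)
  expect_equal(spearman_test(1:8, (1:8)^3)$rho, 1)
  expect_error(spearman_test(1:5, rep(2, 5)), "variance")
  expect_error(spearman_test(1:2, 2:1), ">= 3")
})

test_that("exact p at n = 4 equals full enumeration of the 24 relabelings", {
  set.seed(18)
  for (k in 1:6) {
    x <- sample(1:4); y <- sample(1:4)
    expect_equal(spearman_test(x, y)$p, spearman_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact and t-approximate branches agree to 0.02 at n = 9, |rho| <= 0.6", {
  set.seed(25)
  tested <- 0
  while (tested < 10) {
    x <- 1:9; y <- sample(1:9)
    rho <- cor(x, y, method = "spearman")
    if (abs(rho) > 0.6 || abs(rho) < 0.05) next
    exact_p <- spearman_test(x, y)$p
    tstat <- rho * sqrt((9 - 2) / (1 - rho^2))
    approx_p <- 2 * pt(-abs(tstat), 7)
    expect_lt(abs(exact_p - approx_p), 0.02)
    tested <- tested + 1
  }
})

test_that("correlation matrix is symmetric, with exact self-correlation", {
  set.seed(5)
  env <- env_table(data.frame(a = rnorm(9), b = rnorm(9), c = rnorm(9)),
                   sample_ids = paste0("s", 1:9))
  env$b2 <- env$b
  cm <- correlation_matrix(env)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$p, t(cm$p))
  expect_equal(cm$rho["b", "b2"], 1)
  expect_equal(unname(diag(cm$rho)), rep(1, 4))

  # planted copula correlation is recovered at n = 200
  R <- default_env_correlation()
  envl <- simulate_env(synthetic_config(n_stations = 200, seed = 77))
  cml <- correlation_matrix(envl)
  expect_lt(abs(cml$rho["latitude", "chlorophyll_sum"] -
                R["latitude", "chlorophyll_sum"]), 0.1)
})

test_that("pairwise-complete deletion confines an NA to its own rows", {
  set.seed(9)
  env <- env_table(data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10)),
                   sample_ids = paste0("s", 1:10))
  env_na <- env; env_na$b[3] <- NA
  class(env_na) <- class(env)
  c1 <- correlation_matrix(env); c2 <- correlation_matrix(env_na)
  expect_equal(c1$rho["a", "c"], c2$rho["a", "c"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(c1$rho["a", "b"], c2$rho["a", "b"])))
  expect_equal(c2$n["a", "b"], 9)
})

test_that("drop_low_depth removes exactly the sub-threshold libraries and reports", {
  m <- rbind(r1 = c(a = 25, b = 25), r2 = c(a = 2500, b = 2500),
             r3 = c(a = 3000, b = 3000))
  ct <- count_table(m)
  expect_equal(unclass(drop_low_depth(ct, 0, quiet = TRUE)), unclass(ct),
               ignore_attr = TRUE)
  expect_message(kept <- drop_low_depth(ct, 4941), "r1.*50|removed 1")
  expect_identical(rownames(kept), c("r2", "r3"))
  rep_ <- attr(kept, "removed")
  expect_identical(rep_$sample_id, "r1")
  expect_identical(rep_$depth, 50)
  expect_error(drop_low_depth(ct, 1e7), "no sample")
})

test_that("chlorophyll integration respects the 500 m cutoff", {
  expect_equal(integrate_chlorophyll(data.frame(depth = 100, concentration = 7)), 7)
  prof <- data.frame(depth = seq(100, 600, by = 100),
                     concentration = c(10, 8, 6, 4, 2, 99))
  expect_equal(integrate_chlorophyll(prof), 30)      # 600 m reading excluded
  expect_equal(integrate_chlorophyll(prof, max_depth = 200), 18)
  expect_error(integrate_chlorophyll(prof[0, ]), "empty")
})

test_that("alpha screen has the full grid shape and isolates degeneracies", {
  ds <- simulate_dataset(synthetic_config(seed = 14, n_otus = 60))
  kept <- drop_low_depth(ds$counts, 1000, quiet = TRUE)
  prof <- alpha_profile(kept, ds$tree, depth = 1000, iterations = 2, seed = 1)
  env <- align_env(ds$env, prof$sample_id)
  scr <- alpha_env_screen(prof, env, indices = c("richness", "shannon"))
  expect_equal(nrow(scr), 2 * ncol(as.data.frame(env)) * 2)  # idx x prop x fraction
  expect_true(all(scr$fraction %in% c("DNA", "RNA")))

  # constant index surfaces as an NA row with a note, not an error
  prof2 <- prof; prof2$richness <- 1
  class(prof2) <- class(prof)
  scr2 <- alpha_env_screen(prof2, env, indices = c("richness", "shannon"))
  bad <- scr2[scr2$response == "richness", ]
  expect_true(all(is.na(bad$p)))
  expect_true(all(nzchar(bad$note)))
  expect_true(all(!is.na(scr2$p[scr2$response == "shannon"])))
})

test_that("beta screen covers measures x properties x fractions, never pooling arms", {
  ds <- simulate_dataset(synthetic_config(seed = 16, n_otus = 60))
  kept <- drop_low_depth(ds$counts, 1000, quiet = TRUE)
  scr <- beta_env_screen(kept, ds$env, tree = ds$tree,
                         depths = c(DNA = 1000, RNA = 1000),
                         rarefactions = 2, n_perm = 9, seed = 1,
                         measures = c("bray_weighted", "unifrac_unweighted"),
                         properties = c("chlorophyll_sum", "MnO2", "latitude"))
  expect_equal(nrow(scr), 2 * 3 * 2)
  expect_setequal(unique(scr$fraction), c("DNA", "RNA"))
  expect_true(all(scr$p >= 1 / (1 + 2 * 9) - 1e-12))
  # deterministic given the seed
  scr2 <- beta_env_screen(kept, ds$env, tree = ds$tree,
                          depths = c(DNA = 1000, RNA = 1000),
                          rarefactions = 2, n_perm = 9, seed = 1,
                          measures = c("bray_weighted", "unifrac_unweighted"),
                          properties = c("chlorophyll_sum", "MnO2", "latitude"))
  expect_identical(scr$p, scr2$p)
})

test_that("function screen uses weighted Bray-Curtis without rarefaction", {
  ds <- simulate_dataset(synthetic_config(seed = 22, n_otus = 60))
  scr <- function_screen(ds$functions, ds$env, n_perm = 19, seed = 2,
                         properties = c("chlorophyll_sum", "MnO2"))
  expect_equal(nrow(scr), 2 * 2)
  expect_true(all(scr$measure == "bray_weighted"))

  # identical rows for all samples: F collapses to zero / degenerate NA row
  flat <- matrix(0.05, 6, 20,
                 dimnames = list(paste0("s", 1:6), paste0("f", 1:20)))
  env <- env_table(data.frame(chlorophyll_sum = rnorm(6)),
                   sample_ids = paste0("s", 1:6))
  scr2 <- function_screen(flat, env, n_perm = 9, seed = 1,
                          properties = "chlorophyll_sum")
  expect_true(is.na(scr2$statistic) || scr2$statistic < 1e-10)
})
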