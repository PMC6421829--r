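# Marginal ranges the environmental generator maps onto. Latitude, water
# depth, chlorophyll and the TOC regime follow the transect the package
# emulates (nine abyssal Pacific stations from 27 deg S to 59 deg N, 3,258-
# 5,909 mbsl, chlorophyll 41.9-122.9 mg/m^3 summed over the top 500 m, TOC
# around 0.6% dry weight with a single high value of 1.3% at the northernmost
# station); the remaining sediment properties use plausible deep-sea values.
env_marginals <- function() {
  list(latitude        = c(-27, 59),
       water_depth     = c(3258, 5909),
       chlorophyll_sum = c(41.9, 122.9),
       silicic_acid    = c(60, 180),
       nitrate         = c(30, 45),
       TOC             = c(0.45, 0.80),
       Fe2O3           = c(2, 6),
       MnO2            = c(0.1, 1.5),
       S               = c(0.1, 0.5))
}

# Default target Spearman structure among the covariates: a productivity /
# latitude block (chlorophyll, latitude, silicic acid, nitrate, TOC, S) plus
# a depth-Fe2O3 association. The null property's row is zeroed by
# default_env_correlation() so it stays independent of everything.
default_env_correlation <- function(null_property = "MnO2") {
  props <- names(env_marginals())
  k <- length(props)
  R <- diag(k); dimnames(R) <- list(props, props)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("latitude", "chlorophyll_sum", 0.75)
  set_r("latitude", "silicic_acid", 0.65)
  set_r("latitude", "nitrate", 0.55)
  set_r("latitude", "TOC", 0.50)
  set_r("chlorophyll_sum", "silicic_acid", 0.50)
  set_r("chlorophyll_sum", "nitrate", 0.60)
  set_r("chlorophyll_sum", "TOC", 0.55)
  set_r("silicic_acid", "nitrate", 0.50)
  set_r("nitrate", "TOC", 0.40)
  set_r("TOC", "S", 0.45)
  set_r("water_depth", "Fe2O3", 0.40)
  if (null_property %in% props) {
    R[null_property, ] <- 0; R[, null_property] <- 0
    R[null_property, null_property] <- 1
  }
  R
}

#' Configuration for the synthetic transect generator
#'
#' Bundles every knob of the generator with the defaults that emulate the
#' study transect: 9 stations, paired DNA/RNA libraries with log-uniform
#' depths (one RNA library forced to 50 reads to exercise the low-depth
#' filter), a chlorophyll-driven compositional gradient with phylogenetically
#' correlated zOTU loadings, and a small "Marine-Group-II-like" clade
#' (baseline ~0.3% of the community) enriched 40-fold in the RNA fraction.
#'
#' @param n_stations number of stations (>= 3).
#' @param n_otus number of zOTUs (the full survey had ~1,469; 300 is the
#'   scaled default used throughout the package's own analyses).
#' @param seed integer master seed; it fully determines the dataset.
#' @param depth_range library-depth sampler bounds (reads), log-uniform.
#' @param effect_size_chl slope of the chlorophyll effect on log-abundance
#'   per standardised chlorophyll unit; 0 gives an exchangeable null. The
#'   default is calibrated so the repeated-rarefaction PERMANOVA R2 of
#'   chlorophyll on the DNA arm is ~0.4.
#' @param null_property covariate generated independently of everything,
#'   including composition (default `"MnO2"`).
#' @param rna_mg2_boost multiplicative RNA enrichment of the designated clade.
#' @param mg2_baseline expected DNA-fraction share of the designated clade.
#' @param dispersion Dirichlet-multinomial concentration; smaller is more
#'   overdispersed.
#' @param rna_low_depth forced depth (reads) of the sub-threshold RNA library.
#' @param low_depth_station station index receiving that library.
#' @param env_correlation target Spearman correlation matrix among the nine
#'   covariates (default [default_env_correlation()]); must be positive
#'   definite after the Spearman-to-Pearson copula conversion.
#' @param n_functions number of columns in the synthetic functional table.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_stations = 9, n_otus = 300, seed = 1,
                             depth_range = c(5000, 18000),
                             effect_size_chl = 0.65,
                             null_property = "MnO2",
                             rna_mg2_boost = 40, mg2_baseline = 0.003,
                             dispersion = 200,
                             rna_low_depth = 50, low_depth_station = 2,
                             env_correlation = NULL, n_functions = 20) {
  cfg <- list(n_stations = as.integer(n_stations), n_otus = as.integer(n_otus),
              seed = as.integer(seed), depth_range = depth_range,
              effect_size_chl = effect_size_chl, null_property = null_property,
              rna_mg2_boost = rna_mg2_boost, mg2_baseline = mg2_baseline,
              dispersion = dispersion, rna_low_depth = as.integer(rna_low_depth),
              low_depth_station = as.integer(low_depth_station),
              env_correlation = env_correlation %||% default_env_correlation(null_property),
              n_functions = as.integer(n_functions))
  if (cfg$n_stations < 3) abort("synthetic_config: n_stations must be >= 3")
  if (cfg$n_otus < 2) abort("synthetic_config: n_otus must be >= 2")
  if (cfg$effect_size_chl < 0) abort("synthetic_config: effect_size_chl must be >= 0")
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] > cfg$depth_range[2])
    abort("synthetic_config: depth_range must be c(lo, hi)")
  R <- cfg$env_correlation
  if (!isSymmetric(unname(R)) || !all(diag(R) == 1))
    abort("synthetic_config: env_correlation must be symmetric with unit diagonal")
  P <- 2 * sin(pi * R / 6)        # Spearman -> Pearson for the Gaussian copula
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    abort(paste("synthetic_config: env_correlation is not positive definite",
                "after copula conversion (min eigenvalue %.3g); project it to",
                "the nearest positive-definite matrix (e.g. clip negative",
                "eigenvalues and rescale) and retry"), min(ev))
  cfg$pearson_correlation <- P
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate correlated environmental covariates for a transect
#'
#' A Gaussian copula with the configured rank-correlation target, mapped
#' through uniform quantiles onto each property's marginal range. Stations
#' are relabelled south-to-north (sorted by latitude) and the northernmost
#' station receives the single high TOC value (1.3% dry weight). The null
#' property is drawn independently of everything else.
#'
#' @param config a [synthetic_config()].
#' @return an [env_table()] with `n_stations` rows (`st1` ... `stN`).
#' @export
simulate_env <- function(config) {
  marg <- env_marginals()
  props <- names(marg)
  n <- config$n_stations
  L <- chol(config$pearson_correlation)
  Z <- with_seed(derive_seed(config$seed, 1L),
                 matrix(stats::rnorm(n * length(props)), n) %*% L)
  colnames(Z) <- props
  U <- stats::pnorm(Z)
  vals <- vapply(props, function(p) marg[[p]][1] + U[, p] * diff(marg[[p]]),
                 numeric(n))
  vals <- as.data.frame(vals)
  ord <- order(vals$latitude)
  vals <- vals[ord, , drop = FALSE]
  vals$TOC[n] <- 1.3             # single high TOC at the northernmost station
  env_table(vals, sample_ids = paste0("st", seq_len(n)))
}

#' Simulate a rooted zOTU phylogeny
#'
#' Random topology with exponential branch lengths ([ape::rtree()]), tips
#' labelled `otu0001` ... A small clade (about 2-3% of the tips) is
#' designated as the RNA-enriched "Marine-Group-II-like" group and recorded
#' in the `mg2_tips` attribute.
#'
#' @param config a [synthetic_config()].
#' @return an [ape::phylo] tree with attribute `mg2_tips`.
#' @export
simulate_tree <- function(config) {
  n <- config$n_otus
  tr <- with_seed(derive_seed(config$seed, 2L),
                  ape::rtree(n, br = function(k) stats::rexp(k, rate = 10)))
  tr$tip.label <- sprintf("otu%04d", seq_len(n))
  bt <- branch_table(tr, tr$tip.label)
  sizes <- colSums(bt$M)
  target <- max(3, round(0.025 * n))
  cand <- which(sizes >= 3 & sizes <= max(3, round(0.06 * n)))
  if (!length(cand)) cand <- which(sizes >= 2 & sizes < n)
  pick <- cand[which.min(abs(sizes[cand] - target))]
  attr(tr, "mg2_tips") <- rownames(bt$M)[bt$M[, pick] > 0]
  validate_tree(tr, "simulated tree")
}

# station-level expected compositions (DNA and RNA) under the configured
# chlorophyll effect; returns list(dna, rna) of n_stations x n_otus matrices.
expected_compositions <- function(env, tree, config) {
  n_otus <- config$n_otus
  mg2 <- attr(tree, "mg2_tips")
  base_load <- with_seed(derive_seed(config$seed, 3L), {
    base <- stats::rnorm(n_otus, 0, 1.2)
    names(base) <- tree$tip.label
    load <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    list(base = base, load = load)
  })
  base <- base_load$base
  load <- base_load$load[names(base)]
  load <- (load - mean(load)) / stats::sd(load)
  chl <- env$chlorophyll_sum
  z <- (chl - mean(chl)) / stats::sd(chl)
  tgt <- config$mg2_baseline
  in_mg2 <- names(base) %in% mg2
  dna <- t(vapply(z, function(zs) {
    w <- base + config$effect_size_chl * zs * load
    p <- exp(w - max(w)); p <- p / sum(p)
    # pin the designated clade's share at every station: its DNA-vs-RNA
    # contrast is a fraction effect, deliberately flat along the gradient
    share <- sum(p[in_mg2])
    p[in_mg2] <- p[in_mg2] * (tgt / share)
    p[!in_mg2] <- p[!in_mg2] * ((1 - tgt) / (1 - share))
    p
  }, numeric(n_otus)))
  colnames(dna) <- names(base)
  rna <- dna
  rna[, mg2] <- rna[, mg2] * config$rna_mg2_boost
  rna <- rna / rowSums(rna)
  list(dna = dna, rna = rna)
}

#' Simulate paired DNA/RNA zOTU count libraries
#'
#' Per-station expected composition is `softmax(base + effect_size_chl *
#' standardized(chlorophyll) * loading)` with per-zOTU loadings evolved as
#' Brownian motion along the tree (so phylogenetically close zOTUs respond
#' alike and UniFrac and Bray-Curtis react differently to the gradient).
#' RNA libraries reuse the station composition with the designated clade
#' multiplied by `rna_mg2_boost` and renormalised. Counts are
#' Dirichlet-multinomial at log-uniform library depths; one RNA library is
#' forced to `rna_low_depth` reads so the low-depth filter always has work.
#'
#' @param env station-level [env_table()] from [simulate_env()].
#' @param tree tree from [simulate_tree()] (carries `mg2_tips`).
#' @param config the shared [synthetic_config()].
#' @return a [count_table()] with `2 * n_stations` libraries
#'   (`st1_DNA`, ..., `st1_RNA`, ...), fraction-tagged.
#' @export
simulate_counts <- function(env, tree, config) {
  if (nrow(env) != config$n_stations)
    abort("simulate_counts: env has %d rows, config expects %d stations",
          nrow(env), config$n_stations)
  if (length(tree$tip.label) != config$n_otus)
    abort("simulate_counts: tree has %d tips, config expects %d zOTUs",
          length(tree$tip.label), config$n_otus)
  comp <- expected_compositions(env, tree, config)
  n <- config$n_stations
  with_seed(derive_seed(config$seed, 4L), {
    lo <- log(config$depth_range[1]); hi <- log(config$depth_range[2])
    depths_dna <- round(exp(stats::runif(n, lo, hi)))
    depths_rna <- round(exp(stats::runif(n, lo, hi)))
    depths_rna[config$low_depth_station] <- config$rna_low_depth
    draw <- function(p, depth) {
      a <- stats::rgamma(length(p), shape = p * config$dispersion)
      if (sum(a) == 0) a[] <- 1
      stats::rmultinom(1, depth, a / sum(a))[, 1]
    }
    m <- matrix(0L, 2 * n, config$n_otus,
                dimnames = list(c(paste0(rownames(env), "_DNA"),
                                  paste0(rownames(env), "_RNA")),
                                colnames(comp$dna)))
    for (s in seq_len(n)) {
      m[s, ] <- draw(comp$dna[s, ], depths_dna[s])
      m[n + s, ] <- draw(comp$rna[s, ], depths_rna[s])
    }
    count_table(m, fraction = rep(c("DNA", "RNA"), each = n))
  })
}

#' Simulate a complete transect dataset with known ground truth
#'
#' Runs the environment, tree, count and functional-table generators off one
#' master seed and bundles the result with a truth record naming exactly
#' which covariate structures composition (chlorophyll, with the configured
#' effect size) and which is the planted null. The synthetic functional table
#' is a noisy non-negative linear readout of community composition, present
#' only so the functional screen has a target.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; when given, `counts.tsv`, `env.tsv`,
#'   `tree.nwk`, `functions.tsv` and `truth.json` are written in the
#'   package's file dialects.
#' @return a `synthetic_dataset` list: `counts`, `env` (per-library rows),
#'   `env_stations`, `tree`, `functions`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), dir = NULL) {
  env_st <- simulate_env(config)
  tree <- simulate_tree(config)
  counts <- simulate_counts(env_st, tree, config)
  # per-library env rows: station covariates duplicated across fractions
  idx <- sub("_(DNA|RNA)$", "", rownames(counts))
  env <- env_table(as.data.frame(env_st)[idx, , drop = FALSE],
                   sample_ids = rownames(counts))
  attr(env, "fraction") <- attr(counts, "fraction")
  funs <- with_seed(derive_seed(config$seed, 5L), {
    W <- matrix(stats::rgamma(config$n_otus * config$n_functions, shape = 0.5),
                config$n_otus, config$n_functions)
    P <- unclass(counts) / sample_depths(counts)
    Fm <- P %*% W
    Fm <- Fm * exp(matrix(stats::rnorm(length(Fm), 0, 0.1), nrow(Fm)))
    Fm <- Fm / rowSums(Fm)
    colnames(Fm) <- sprintf("fn%03d", seq_len(config$n_functions))
    Fm
  })
  attr(funs, "fraction") <- attr(counts, "fraction")
  truth <- list(structuring = "chlorophyll_sum",
                effect_size_chl = config$effect_size_chl,
                null_property = config$null_property,
                mg2_otus = attr(tree, "mg2_tips"),
                low_depth_sample = paste0(rownames(env_st)[config$low_depth_station], "_RNA"),
                seed = config$seed)
  ds <- structure(list(counts = counts, env = env, env_stations = env_st,
                       tree = tree, functions = funs, truth = truth,
                       config = config),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a synthetic dataset's files
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(ds$counts, file.path(dir, "counts.tsv"))
  write_env_table(ds$env, file.path(dir, "env.tsv"))
  write_tree(ds$tree, file.path(dir, "tree.nwk"))
  fdf <- data.frame(sample_id = rownames(ds$functions), ds$functions,
                    check.names = FALSE)
  utils::write.table(fdf, file.path(dir, "functions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d stations, %d zOTUs, seed %d\n",
              x$config$n_stations, x$config$n_otus, x$config$seed))
  cat(sprintf("  structuring covariate: %s (effect %.3g); null: %s\n",
              x$truth$structuring, x$truth$effect_size_chl, x$truth$null_property))
  print(x$counts)
  invisible(x)
}
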