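#' Build or read a pipeline configuration
#'
#' Either the path of a YAML file or a list of overrides. Defaults follow the
#' study protocol: rarefaction depths 9,058 (DNA) / 4,941 (RNA), 100
#' alpha-diversity iterations, 999 rarefactions x 999 permutations for the
#' PERMANOVA screens, significance at p <= 0.05. `depths = "auto"` (the
#' default when a `simulate` block is present) sets each fraction's depth to
#' the minimum library size at or above `min_depth_floor`, mirroring how the
#' study's depths were chosen. `profile = "desk"` shrinks the replication
#' (rarefactions 50, permutations 99, iterations 20) for quick runs.
#'
#' @param config YAML path, list of overrides, or `NULL` for pure defaults.
#' @return a `pipeline_config` list; it round-trips losslessly through
#'   [yaml::write_yaml()] / [yaml::read_yaml()].
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  defaults <- list(
    inputs = NULL,                 # list(counts=, env=, tree=, functions=)
    simulate = NULL,               # overrides for synthetic_config()
    depths = list(DNA = 9058, RNA = 4941),
    min_depth_floor = 1000,
    iterations = 100,
    rarefactions = 999,
    permutations = 999,
    alpha = 0.05,
    measures = c("bray_weighted", "bray_unweighted",
                 "unifrac_weighted", "unifrac_unweighted"),
    seed = 1,
    outdir = "benthodiv_run",
    profile = "full")
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(cfg$simulate) && is.null(config$depths)) cfg$depths <- "auto"
  if (identical(cfg$profile, "desk")) {
    if (is.null(config$rarefactions)) cfg$rarefactions <- 50
    if (is.null(config$permutations)) cfg$permutations <- 99
    if (is.null(config$iterations)) cfg$iterations <- 20
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    abort("pipeline_config: need either an 'inputs' block or a 'simulate' block")
  bad <- setdiff(cfg$measures,
                 c("bray_weighted", "bray_unweighted",
                   "unifrac_weighted", "unifrac_unweighted"))
  if (length(bad)) abort("pipeline_config: unknown measure(s): %s",
                         paste(bad, collapse = ", "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# hash over the analysis-relevant configuration: the output location does not
# influence any result, so it is excluded
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates data acquisition (simulation or loading), low-depth
#' filtering, repeated-rarefaction alpha diversity, the environmental
#' correlation matrix, the alpha-vs-environment Spearman screen, the
#' four-measure repeated-rarefaction PERMANOVA screen, and (when a
#' functional table exists) the functional Bray-Curtis screen. Every stage
#' writes its outputs into `config$outdir`; `manifest.json` records the
#' config hash, seed, per-stage status and wall time, and an md5 of every
#' output file. With `resume = TRUE` a stage whose outputs already exist is
#' skipped.
#'
#' @param config a [pipeline_config()] (or YAML path / override list).
#' @param resume skip stages whose outputs are already on disk.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, resume = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  hash <- config_hash(cfg)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))
  old_opt <- options(benthodiv.config_hash = hash)
  on.exit(options(old_opt))
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  manifest <- list(benthodiv = as.character(utils::packageVersion("benthodiv")),
                   config_hash = hash, seed = cfg$seed, stages = list(),
                   timing = list())
  run_stage <- function(name, outputs, fun) {
    paths <- file.path(out, outputs)
    if (resume && all(file.exists(paths))) {
      logf("stage %s: resumed (outputs present)", name)
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- "done"
    manifest$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logf("stage %s: done (%.1fs)", name, manifest$timing[[name]])
    res
  }

  # ---- pre-flight validation, before any computation
  needs_tree <- any(startsWith(cfg$measures, "unifrac"))
  if (is.null(cfg$simulate)) {
    for (key in c("counts", "env")) if (is.null(cfg$inputs[[key]]))
      abort("pipeline: inputs$%s is required", key)
    if (needs_tree && is.null(cfg$inputs$tree))
      abort("pipeline: UniFrac measure requested but no tree given")
  }

  # ---- stage: data
  datadir <- file.path(out, "data")
  run_stage("data", file.path("data", "counts.tsv"), function() {
    if (!is.null(cfg$simulate)) {
      scfg <- do.call(synthetic_config,
                      utils::modifyList(list(seed = cfg$seed), cfg$simulate))
      simulate_dataset(scfg, dir = datadir)
    } else {
      dir.create(datadir, recursive = TRUE, showWarnings = FALSE)
      file.copy(cfg$inputs$counts, file.path(datadir, "counts.tsv"), overwrite = TRUE)
      file.copy(cfg$inputs$env, file.path(datadir, "env.tsv"), overwrite = TRUE)
      if (!is.null(cfg$inputs$tree))
        file.copy(cfg$inputs$tree, file.path(datadir, "tree.nwk"), overwrite = TRUE)
      if (!is.null(cfg$inputs$functions))
        file.copy(cfg$inputs$functions, file.path(datadir, "functions.tsv"),
                  overwrite = TRUE)
    }
  })
  counts <- read_count_table(file.path(datadir, "counts.tsv"), quiet = TRUE)
  env <- read_env_table(file.path(datadir, "env.tsv"), counts = counts, quiet = TRUE)
  tree <- if (file.exists(file.path(datadir, "tree.nwk")))
    read_tree(file.path(datadir, "tree.nwk"))
  funs_path <- file.path(datadir, "functions.tsv")

  # ---- stage: filter (per fraction, at the rarefaction depth)
  fracs <- if (is.null(attr(counts, "fraction"))) stats::setNames(NA_character_, "all") else
    intersect(c("DNA", "RNA"), unique(attr(counts, "fraction")))
  depths <- cfg$depths
  if (identical(depths, "auto")) {
    depths <- lapply(stats::setNames(fracs, fracs), function(fr) {
      sub <- if (is.na(fr)) counts else subset_fraction(counts, fr)
      d <- sample_depths(sub)
      keep <- d[d >= cfg$min_depth_floor]
      if (!length(keep)) abort("pipeline: no %s library reaches the depth floor %d",
                               fr, cfg$min_depth_floor)
      min(keep)
    })
  }
  filtered <- list()
  run_stage("filter", "filter_report.json", function() {
    report <- list()
    for (fr in fracs) {
      sub <- if (is.na(fr)) counts else subset_fraction(counts, fr)
      depth <- if (is.na(fr)) depths[[1L]] else depths[[fr]]
      kept <- drop_low_depth(sub, depth, quiet = TRUE)
      filtered[[if (is.na(fr)) "all" else fr]] <<- kept
      report[[if (is.na(fr)) "all" else fr]] <-
        list(depth = depth, n_kept = nrow(kept),
             removed = attr(kept, "removed"))
      rem <- attr(kept, "removed")
      if (nrow(rem)) logf("filter %s: removed %s", fr,
                          paste(sprintf("%s (%d reads)", rem$sample_id, rem$depth),
                                collapse = ", "))
    }
    jsonlite::write_json(report, file.path(out, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  if (!length(filtered)) {   # resumed: rebuild in memory
    for (fr in fracs) {
      sub <- if (is.na(fr)) counts else subset_fraction(counts, fr)
      depth <- if (is.na(fr)) depths[[1L]] else depths[[fr]]
      filtered[[if (is.na(fr)) "all" else fr]] <- drop_low_depth(sub, depth, quiet = TRUE)
    }
  }
  kept_all <- do.call(rbind, lapply(filtered, function(ct) unclass(ct)))
  kept_ct <- count_table(kept_all,
                         fraction = if (!is.na(fracs[1]))
                           do.call(c, unname(lapply(filtered, function(ct)
                             attr(ct, "fraction")))))

  # ---- stage: alpha diversity
  run_stage("alpha", "alpha_profile.tsv", function() {
    profs <- lapply(names(filtered), function(key) {
      depth <- if (key == "all") depths[[1L]] else depths[[key]]
      alpha_profile(filtered[[key]], tree, depth = depth,
                    iterations = cfg$iterations,
                    seed = derive_seed(cfg$seed, match(key, names(filtered))))
    })
    combined <- do.call(rbind, lapply(profs, as.data.frame))
    attr(combined, "depth") <- depths[[1L]]
    attr(combined, "iterations") <- cfg$iterations
    attr(combined, "seed") <- cfg$seed
    class(combined) <- c("alpha_profile", "data.frame")
    write_results(combined, file.path(out, "alpha_profile.tsv"))
  })

  # ---- stage: environmental correlation matrix
  run_stage("env_corr", "fig_env_corr.tsv", function() {
    env_st <- unique(as.data.frame(env))
    write_results(correlation_matrix(env_st, alpha = cfg$alpha),
                  file.path(out, "fig_env_corr.tsv"))
  })

  # ---- stage: alpha-diversity vs environment screen
  run_stage("alpha_screen", "fig_alpha_screen.tsv", function() {
    prof <- read_alpha_profile(file.path(out, "alpha_profile.tsv"))
    write_results(alpha_env_screen(prof, align_env(env, prof$sample_id),
                                   alpha_level = cfg$alpha),
                  file.path(out, "fig_alpha_screen.tsv"))
  })

  # ---- stage: composition vs environment PERMANOVA screen
  run_stage("beta_screen", "fig_beta_screen.tsv", function() {
    write_results(beta_env_screen(kept_ct, env, tree = tree, depths = depths,
                                  rarefactions = cfg$rarefactions,
                                  n_perm = cfg$permutations,
                                  seed = cfg$seed, measures = cfg$measures,
                                  alpha_level = cfg$alpha),
                  file.path(out, "fig_beta_screen.tsv"))
  })

  # ---- stage: functional screen (optional)
  if (file.exists(funs_path)) {
    run_stage("function_screen", "fig_function_screen.tsv", function() {
      fdf <- utils::read.delim(funs_path, check.names = FALSE, comment.char = "#")
      fm <- as.matrix(fdf[, -1, drop = FALSE])
      rownames(fm) <- fdf[[1]]
      fm <- fm[intersect(rownames(kept_ct), rownames(fm)), , drop = FALSE]
      fr <- attr(kept_ct, "fraction")
      write_results(function_screen(fm, env,
                                    fraction = if (!is.null(fr)) fr[rownames(fm)],
                                    n_perm = cfg$permutations,
                                    seed = derive_seed(cfg$seed, 7L),
                                    alpha_level = cfg$alpha),
                    file.path(out, "fig_function_screen.tsv"))
    })
  }

  files <- setdiff(list.files(out, recursive = TRUE),
                   c("manifest.json", "run.log", "config.yaml"))
  manifest$files <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out, f))))
  manifest$depths <- depths
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# read back an alpha_profile.tsv written by write_results
read_alpha_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  class(df) <- c("alpha_profile", "data.frame")
  df
}
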