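#' Write an analysis result to disk
#'
#' Matrices and tables go to TSV (with a `#`-prefixed metadata header naming
#' the package version and the object's parameters, which the package's own
#' readers skip); structured single results go to JSON. Column order is
#' deterministic.
#'
#' @param x a result object (`comm_dist`, `permanova`, `alpha_profile`,
#'   `screen_table`, `env_corr`, or any list).
#' @param path output file.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

result_header <- function(...) {
  kv <- c(list(benthodiv = as.character(utils::packageVersion("benthodiv"))),
          Filter(Negate(is.null),
                 c(list(config_hash = getOption("benthodiv.config_hash")),
                   list(...))))
  paste0("# ", names(kv), ": ", vapply(kv, function(v) paste(format(v), collapse = ","),
                                       character(1)))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.comm_dist <- function(x, path, ...) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  write_tsv_with_header(df, path, result_header(measure = attr(x, "measure")))
}

#' @export
write_results.permanova <- function(x, path, ...) {
  out <- x[c("covariate", "F", "R2", "p", "df_model", "df_resid",
             "n_perm", "n_rarefactions", "epsilon", "measure", "seed")]
  out$benthodiv <- as.character(utils::packageVersion("benthodiv"))
  out$config_hash <- getOption("benthodiv.config_hash")
  if (!is.null(x$trace)) out$trace <- x$trace
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @export
write_results.alpha_profile <- function(x, path, ...) {
  write_tsv_with_header(as.data.frame(x), path,
                        result_header(depth = attr(x, "depth"),
                                      iterations = attr(x, "iterations"),
                                      seed = attr(x, "seed")))
}

#' @export
write_results.screen_table <- function(x, path, ...) {
  write_tsv_with_header(as.data.frame(x), path,
                        result_header(statistic = attr(x, "statistic"),
                                      alpha = attr(x, "alpha"),
                                      rarefactions = attr(x, "rarefactions"),
                                      n_perm = attr(x, "n_perm"),
                                      seed = attr(x, "seed")))
}

#' @export
write_results.env_corr <- function(x, path, ...) {
  write_tsv_with_header(x$table, path, result_header(alpha = x$alpha))
}

#' @export
write_results.default <- function(x, path, ...) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
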