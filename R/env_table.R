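#' Construct an environmental-covariate table
#'
#' One row per sample, one numeric column per measured property (latitude in
#' signed degrees, water depth in mbsl, chlorophyll summed over the top 500 m
#' of the water column in mg/m^3, silicic acid and nitrate in uM, TOC as % of
#' sediment dry weight, and the sediment Fe2O3/MnO2/S contents). Missing
#' measurements stay `NA` and are handled pairwise downstream, never silently
#' zeroed.
#'
#' @param properties data.frame of numeric columns.
#' @param sample_ids character sample labels (default: rownames).
#' @return an `env_table` (a data.frame with sample ids as rownames).
#' @export
env_table <- function(properties, sample_ids = rownames(properties)) {
  properties <- as.data.frame(properties)
  if (is.null(sample_ids)) abort("env table needs sample labels")
  if (anyDuplicated(sample_ids)) abort("duplicate sample labels in env table")
  ok <- vapply(properties, is.numeric, logical(1))
  if (!all(ok)) abort("non-numeric env property column(s): %s",
                      paste(names(properties)[!ok], collapse = ", "))
  rownames(properties) <- sample_ids
  class(properties) <- c("env_table", "data.frame")
  properties
}

#' Read an environmental table from TSV
#'
#' First column sample labels, remaining columns numeric properties; the
#' literal token `NA` (or an empty cell) marks a missing measurement.
#'
#' @param path TSV file.
#' @param counts optional companion [count_table()]; env labels absent from it
#'   trigger a warning listing the orphans.
#' @param quiet suppress the parse report (which also flags columns with NAs).
#' @return an `env_table`.
#' @export
read_env_table <- function(path, counts = NULL, quiet = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("'%s': need a label column plus at least one property", path)
  labs <- as.character(df[[1L]])
  props <- df[, -1L, drop = FALSE]
  # keep a non-numeric 'fraction' column aside if present
  frac <- NULL
  if ("fraction" %in% names(props)) {
    frac <- as.character(props[["fraction"]])
    props[["fraction"]] <- NULL
  }
  props[] <- lapply(props, function(col) suppressWarnings(as.numeric(col)))
  env <- env_table(props, sample_ids = labs)
  if (!is.null(frac)) attr(env, "fraction") <- stats::setNames(frac, labs)
  if (!is.null(counts)) {
    orphans <- setdiff(labs, rownames(counts))
    if (length(orphans))
      warning("env samples absent from count table: ",
              paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    with_na <- names(props)[vapply(props, anyNA, logical(1))]
    message(sprintf("read_env_table: %d samples, %d properties%s",
                    nrow(env), ncol(env),
                    if (length(with_na)) paste0("; NA in: ", paste(with_na, collapse = ", "))
                    else ""))
  }
  env
}

#' Write an environmental table to TSV
#' @param x an `env_table`.
#' @param path output file.
#' @export
write_env_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(x), check.names = FALSE)
  fr <- attr(x, "fraction")
  if (!is.null(fr)) df$fraction <- fr[rownames(x)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an env table to a count table by sample label
#'
#' Alignment is always by label, never by row position, so shuffling env rows
#' can never change a downstream result.
#' @param env an `env_table`.
#' @param counts a `count_table` (or anything with rownames), or a character
#'   vector of sample ids.
#' @return the env table reordered to the count table's samples.
#' @export
align_env <- function(env, counts) {
  ids <- if (is.character(counts)) counts else rownames(counts)
  missing <- setdiff(ids, rownames(env))
  if (length(missing))
    abort("env table lacks samples: %s", paste(missing, collapse = ", "))
  out <- env[ids, , drop = FALSE]
  class(out) <- class(env)
  fr <- attr(env, "fraction")
  if (!is.null(fr)) attr(out, "fraction") <- fr[ids]
  out
}
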