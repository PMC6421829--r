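#' Construct a community count table
#'
#' The central data container of the package: a samples-in-rows matrix of
#' non-negative integer read counts over zOTUs (zero-radius OTUs, i.e.
#' denoised exact sequence variants), optionally tagged with the nucleic-acid
#' fraction each library was sequenced from (`"DNA"` for the entire community,
#' `"RNA"` for the potentially active community).
#'
#' @param counts numeric matrix of non-negative integers, samples in rows,
#'   zOTUs in columns, with unique dimnames.
#' @param fraction optional character vector (one per sample, or named by
#'   sample id) with values `"DNA"` or `"RNA"`.
#' @return an object of class `count_table`: the integer matrix with
#'   attributes `fraction`.
#' @examples
#' ct <- count_table(matrix(c(1, 2, 3, 0, 4, 0), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
#' sample_depths(ct)
#' @export
count_table <- function(counts, fraction = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("count table needs sample (row) and zOTU (column) names")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate sample labels: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort("duplicate zOTU labels: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    abort("counts must be numeric with no missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    abort("non-negative integer counts required; first offender: sample '%s', zOTU '%s' (value %s)",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
          format(counts[bad[1, , drop = FALSE]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(fraction)) {
    if (!is.null(names(fraction))) fraction <- fraction[rownames(counts)]
    fraction <- as.character(fraction)
    if (length(fraction) != nrow(counts) || anyNA(fraction) ||
        !all(fraction %in% c("DNA", "RNA")))
      abort("fraction must assign 'DNA' or 'RNA' to every sample")
    names(fraction) <- rownames(counts)
  }
  structure(counts, fraction = fraction, class = c("count_table", "matrix", "array"))
}

#' Library depths (row sums) of a count table
#' @param x a `count_table` (or plain count matrix).
#' @return named integer vector of per-sample read totals.
#' @export
sample_depths <- function(x) {
  d <- rowSums(unclass(x))
  storage.mode(d) <- "double"
  d
}

#' Subset a count table by sample
#'
#' Row subsetting keeps the class and the fraction tags aligned; any other
#' subsetting drops to a plain matrix.
#' @param x a `count_table`.
#' @param i,j,... row/column indices.
#' @param drop ignored for row-only subsetting.
#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  fr <- attr(x, "fraction")
  m <- unclass(x)
  if (missing(j)) {
    m <- m[i, , drop = FALSE]
    if (!is.null(fr)) fr <- fr[rownames(m)]
    return(structure(m, fraction = fr, class = class(x)))
  }
  m[i, j, drop = drop]
}

#' @export
print.count_table <- function(x, ...) {
  d <- sample_depths(x)
  fr <- attr(x, "fraction")
  cat(sprintf("count_table: %d samples x %d zOTUs; depth %s-%s\n",
              nrow(x), ncol(x), format(min(d)), format(max(d))))
  if (!is.null(fr)) cat("fractions:", paste(sprintf("%s=%d", names(table(fr)), table(fr)),
                                            collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a count table to one nucleic-acid fraction
#' @param x a `count_table` with fraction tags.
#' @param fraction `"DNA"` or `"RNA"`.
#' @export
subset_fraction <- function(x, fraction) {
  fr <- attr(x, "fraction")
  if (is.null(fr)) abort("count table carries no fraction tags")
  x[fr == fraction, ]
}

#' Read a sample x zOTU count table from TSV
#'
#' Expects a header row; the first column holds sample labels (or zOTU labels
#' with `transpose = TRUE` for the OTUs-in-rows dialect). All remaining cells
#' must be non-negative integers.
#'
#' @param path TSV file.
#' @param transpose set `TRUE` if the file stores zOTUs in rows.
#' @param fraction optional fraction tags, as in [count_table()]; if `NULL`
#'   and all sample labels end in `_DNA`/`_RNA` the tags are inferred.
#' @param quiet suppress the one-line parse report.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, transpose = FALSE, fraction = NULL, quiet = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("'%s': need a label column plus at least one count column", path)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    abort("'%s': non-numeric count cell at row '%s', column '%s'", path,
          labs[bad[1, 1]], colnames(df)[-1L][bad[1, 2]])
  }
  rownames(m) <- labs
  if (transpose) m <- t(m)
  if (is.null(fraction) && all(grepl("_(DNA|RNA)$", rownames(m))))
    fraction <- sub(".*_", "", rownames(m))
  ct <- count_table(m, fraction = fraction)
  if (!quiet) {
    d <- sample_depths(ct)
    message(sprintf("read_count_table: %d samples, %d zOTUs, depths %s-%s",
                    nrow(ct), ncol(ct), format(min(d)), format(max(d))))
  }
  ct
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; the round trip is lossless.
#' @param x a `count_table`.
#' @param path output file.
#' @param transpose write the zOTUs-in-rows dialect.
#' @export
write_count_table <- function(x, path, transpose = FALSE) {
  m <- unclass(x)
  if (transpose) m <- t(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- if (transpose) "otu_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
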