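#' Feature-by-sample counts matrix
#'
#' Nonnegative integer counts with per-sample condition/replicate labels,
#' the interface object for RNA-seq gene counts, per-copy transposon
#' counts, and CUT&RUN feature counts alike.
#'
#' @param counts Integer matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param condition Character vector, one condition label per column.
#' @param replicate Optional integer replicate index per column.
#' @return An object of class `counts_matrix` with fields `counts` and
#'   `samples`.
#' @export
counts_matrix <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique row names (feature ids)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique column names (sample ids)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(condition) != ncol(counts))
    stop("one condition label per sample required")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  structure(list(counts = counts,
                 samples = data.frame(sample = colnames(counts),
                                      condition = as.character(condition),
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat("<counts_matrix> ", nrow(x$counts), " feature(s) x ", ncol(x$counts),
      " sample(s); conditions: ",
      paste(unique(x$samples$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' Columns of a counts matrix belonging to a condition
#' @param cm A [counts_matrix()].
#' @param condition Condition label.
#' @export
condition_samples <- function(cm, condition) {
  idx <- which(cm$samples$condition == condition)
  if (length(idx) == 0) stop("no samples for condition '", condition, "'")
  idx
}

#' Median-of-ratios size factors
#'
#' Library-size normalization factors: the reference is the per-feature
#' geometric mean over features with positive counts in every sample; each
#' sample's factor is the median of its count/reference ratios. Normalized
#' counts are `counts / factor`.
#'
#' @param cm A [counts_matrix()] or plain counts matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(cm) {
  mat <- if (inherits(cm, "counts_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos))
    stop("no feature has positive counts in every sample")
  logref <- rowMeans(log(mat[all_pos, , drop = FALSE]))
  sf <- apply(mat[all_pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logref)))
  sf
}

#' Size-factor-normalized counts
#' @param cm A [counts_matrix()].
#' @param sf Optional precomputed [size_factors()].
#' @return Numeric matrix of normalized counts.
#' @export
normalized_counts <- function(cm, sf = NULL) {
  mat <- if (inherits(cm, "counts_matrix")) cm$counts else as.matrix(cm)
  if (is.null(sf)) sf <- size_factors(cm)
  sweep(mat, 2, sf, `/`)
}

#' Read / write a counts matrix as TSV
#' @param path File path. The first column holds feature ids; a `#condition`
#'   comment line above the header records per-sample conditions.
#' @param cm A [counts_matrix()] (writer only).
#' @export
write_counts_tsv <- function(cm, path) {
  con <- file(path, "w")
  writeLines(paste0("#condition\t",
                    paste(cm$samples$condition, collapse = "\t")), con)
  utils::write.table(cbind(feature = rownames(cm$counts), cm$counts), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  first <- readLines(path, n = 1)
  cond <- NULL
  skip <- 0
  if (startsWith(first, "#condition")) {
    cond <- strsplit(first, "\t")[[1]][-1]
    skip <- 1
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                           check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  if (is.null(cond)) cond <- rep("unknown", ncol(mat))
  counts_matrix(mat, cond)
}
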