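#' Transposable-element copy table
#'
#' Validates a data.frame of individual TE copies: `copy_id`, `family`,
#' `chrom`, `start`, `end`, optional `strand`.
#'
#' @param copies data.frame of TE copies.
#' @return The validated data.frame with a `length` column.
#' @export
te_copy_table <- function(copies) {
  req <- c("copy_id", "family", "chrom", "start", "end")
  if (!all(req %in% names(copies)))
    stop("copies must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(copies$copy_id)) stop("copy ids must be unique")
  if (any(copies$start >= copies$end)) stop("copy start must be < end")
  if (is.null(copies$strand)) copies$strand <- "*"
  copies$length <- copies$end - copies$start + 1
  copies
}

#' Call derepressed TE copies between two conditions
#'
#' Counts are size-factor normalized; each copy's fold change is
#' `(mean_B + pc) / (mean_A + pc)` with pseudocount `pc` of one normalized
#' count (copy-level counts are frequently zero). Significance comes from
#' an injected differential-expression table when supplied, otherwise from
#' a Welch t test on log1p normalized counts with Benjamini-Hochberg
#' adjustment. A copy is called `up` when its fold change reaches
#' `fold_threshold` (inclusive: "at least n-fold") and is significant at
#' `alpha`.
#'
#' @param copies A [te_copy_table()] data.frame.
#' @param cm A [counts_matrix()] over the copies, covering both conditions.
#' @param cond_a,cond_b Condition labels (fold change is B over A).
#' @param fold_threshold Minimum fold induction, default 10.
#' @param alpha Adjusted-significance cutoff, default 0.05.
#' @param pseudocount Added to both means before the ratio, default 1.
#' @param de_table Optional data.frame with `copy_id` and `padj` columns
#'   from an external differential-expression engine.
#' @return data.frame with one row per quantified copy: `copy_id`,
#'   `family`, `mean_a`, `mean_b`, `fold`, `padj`, `called`
#'   ("up"/"unchanged").
#' @export
call_derepressed <- function(copies, cm, cond_a, cond_b,
                             fold_threshold = 10, alpha = 0.05,
                             pseudocount = 1, de_table = NULL) {
  copies <- te_copy_table(copies)
  missing <- setdiff(copies$copy_id, rownames(cm$counts))
  if (length(missing)) {
    warning(length(missing), " copies absent from the counts table; excluded")
    copies <- copies[!copies$copy_id %in% missing, , drop = FALSE]
  }
  idx_a <- condition_samples(cm, cond_a)
  idx_b <- condition_samples(cm, cond_b)
  norm <- normalized_counts(cm)[copies$copy_id, , drop = FALSE]
  mean_a <- rowMeans(norm[, idx_a, drop = FALSE])
  mean_b <- rowMeans(norm[, idx_b, drop = FALSE])
  fold <- (mean_b + pseudocount) / (mean_a + pseudocount)

  if (!is.null(de_table)) {
    padj <- setNames(de_table$padj, de_table$copy_id)[copies$copy_id]
  } else {
    pvals <- vapply(seq_len(nrow(copies)), function(i) {
      a <- log1p(norm[i, idx_a])
      b <- log1p(norm[i, idx_b])
      if (sd(a) == 0 && sd(b) == 0)
        return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 1e-12)
      tryCatch(t.test(b, a)$p.value, error = function(e) 1)
    }, numeric(1))
    padj <- p.adjust(pvals, method = "BH")
  }
  called <- ifelse(fold >= fold_threshold & !is.na(padj) & padj < alpha,
                   "up", "unchanged")
  data.frame(copy_id = copies$copy_id, family = copies$family,
             mean_a = mean_a, mean_b = mean_b, fold = fold, padj = padj,
             called = called, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare H3K9me2 levels on derepressed versus unchanged copies
#'
#' Splits per-copy normalized H3K9me2 counts (averaged over the replicates
#' of `condition`) by derepression call status and applies the
#' Kruskal-Wallis / Dunn comparison.
#'
#' @param k9_cm A [counts_matrix()] of H3K9me2 CUT&RUN counts over the
#'   same copies.
#' @param calls A [call_derepressed()] result.
#' @param condition Condition whose replicates are averaged.
#' @param normalize Size-factor normalize `k9_cm` first (default TRUE; set
#'   FALSE when the matrix is already normalized).
#' @return A [compare_groups()] result with groups `up` and `unchanged`.
#' @export
k9_on_copy_sets <- function(k9_cm, calls, condition, normalize = TRUE) {
  idx <- condition_samples(k9_cm, condition)
  mat <- if (normalize) normalized_counts(k9_cm) else k9_cm$counts
  shared <- intersect(calls$copy_id, rownames(mat))
  vals <- rowMeans(mat[shared, idx, drop = FALSE])
  status <- setNames(calls$called, calls$copy_id)[shared]
  groups <- split(unname(vals), status)
  if (!all(c("up", "unchanged") %in% names(groups)))
    stop("both an up-called and an unchanged copy set are required")
  compare_groups(groups[c("unchanged", "up")])
}
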