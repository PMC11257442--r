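#' Gene model table
#'
#' Validates a data.frame of gene models: `gene_id`, `chrom`, `start`,
#' `end` (1-based closed), `strand`, and `effective_length` in bp (the
#' length used for TPM; union-exon length when exon structure is known,
#' locus width otherwise).
#'
#' @param genes data.frame with at least gene_id/chrom/start/end.
#' @return The validated data.frame.
#' @export
gene_table <- function(genes) {
  req <- c("gene_id", "chrom", "start", "end")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  if (is.null(genes$strand)) genes$strand <- "*"
  if (is.null(genes$effective_length))
    genes$effective_length <- genes$end - genes$start + 1
  if (any(genes$effective_length <= 0))
    stop("effective_length must be positive")
  genes
}

#' Read gene models from GTF or BED
#'
#' GTF: `gene` rows define loci; effective length is the union-exon length
#' when `exon` rows are present, else the locus width. BED: intervals with
#' the name column as gene id.
#'
#' @param path Annotation file (.gtf/.gff or .bed).
#' @param format `"gtf"` or `"bed"`; guessed from the extension by default.
#' @return A [gene_table()] data.frame.
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "gtf"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.frame(gene_id = gr$name,
                        chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    return(gene_table(genes))
  }
  gr <- rtracklayer::import(path, format = "GTF")
  g <- gr[gr$type == "gene"]
  if (length(g) == 0) stop("no 'gene' rows in GTF file")
  genes <- data.frame(gene_id = g$gene_id,
                      chrom = as.character(GenomeInfoDb::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE)
  ex <- gr[gr$type == "exon"]
  if (length(ex) > 0) {
    exl <- vapply(split(GenomicRanges::granges(ex), ex$gene_id),
                  function(x) sum(GenomicRanges::width(GenomicRanges::reduce(x))),
                  numeric(1))
    genes$effective_length <- unname(exl[genes$gene_id])
    genes$effective_length[is.na(genes$effective_length)] <-
      (genes$end - genes$start + 1)[is.na(genes$effective_length)]
  }
  gene_table(genes)
}

#' @keywords internal
.features_to_granges <- function(feats, id_col = "gene_id") {
  GenomicRanges::GRanges(feats$chrom,
                         IRanges::IRanges(feats$start, feats$end),
                         id = feats[[id_col]])
}

#' Assign genes to domain classes
#'
#' Each gene is categorized `outside`, `class1` or `class2` by the rule
#' chosen: `"majority"` (default) takes the category covering the most
#' gene-body bp, with a class1/class2 bp tie going to class2 and a
#' domain/outside tie going to the domain class; `"any_overlap"` places a
#' gene in the domain class it overlaps at all (most-overlapped class when
#' both).
#'
#' @param genes A [gene_table()] data.frame.
#' @param domains A domain set `GRanges`.
#' @param rule `"majority"` or `"any_overlap"`.
#' @param layout Optional [genome_layout()]; genes outside it are an error.
#' @return data.frame with `gene_id` and `category` (factor with levels
#'   outside/class1/class2).
#' @export
assign_genes <- function(genes, domains, rule = c("majority", "any_overlap"),
                         layout = NULL) {
  rule <- match.arg(rule)
  genes <- gene_table(genes)
  if (!is.null(layout)) {
    if (!all(genes$chrom %in% layout$chrom) ||
        any(genes$end > layout$length[genes$chrom]) || any(genes$start < 1))
      stop("gene outside the genome layout")
  }
  gr <- .features_to_granges(genes)
  bp_by_class <- function(cl) {
    sub <- granges_clean(domains[domains$class == cl])
    out <- numeric(length(gr))
    hit <- GenomicRanges::findOverlaps(gr, sub)
    if (length(hit)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[S4Vectors::queryHits(hit)], sub[S4Vectors::subjectHits(hit)]))
      agg <- tapply(ov, S4Vectors::queryHits(hit), sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }
  bp1 <- bp_by_class("class1")
  bp2 <- bp_by_class("class2")
  out_bp <- GenomicRanges::width(gr) - bp1 - bp2
  dom_class <- ifelse(bp2 >= bp1, "class2", "class1")
  best_dom <- pmax(bp1, bp2)
  category <- switch(rule,
    majority = ifelse(best_dom > 0 & best_dom >= out_bp, dom_class, "outside"),
    any_overlap = ifelse(bp1 + bp2 > 0, dom_class, "outside"))
  data.frame(gene_id = genes$gene_id,
             category = factor(category,
                               levels = c("outside", "class1", "class2")),
             stringsAsFactors = FALSE)
}

#' Transcripts-per-million expression matrix
#'
#' Per sample: each gene's count is divided by its effective length in kb,
#' and the rates are normalized to sum to one million.
#'
#' @param cm A [counts_matrix()] over genes.
#' @param genes A [gene_table()] data.frame covering all features of `cm`.
#' @return Numeric matrix of TPM values (columns sum to 1e6).
#' @export
tpm <- function(cm, genes) {
  genes <- gene_table(genes)
  mat <- cm$counts
  len <- setNames(genes$effective_length, genes$gene_id)[rownames(mat)]
  if (any(is.na(len)))
    stop("every counted feature needs an effective_length")
  rate <- mat / (len / 1000)
  cs <- colSums(rate)
  if (any(cs == 0)) stop("zero total rate in a sample; cannot compute TPM")
  sweep(rate, 2, cs, `/`) * 1e6
}

#' Fraction of genes expressed per domain category
#'
#' A gene counts as expressed when its mean TPM over the replicates of
#' `condition` reaches `threshold` (5 TPM in the reference workflow).
#'
#' @param assignment An [assign_genes()] result.
#' @param tpm_matrix A [tpm()] matrix.
#' @param cm The [counts_matrix()] the TPM matrix came from (for sample
#'   conditions).
#' @param condition Condition label to average over.
#' @param threshold Expression threshold in TPM, default 5.
#' @return Named numeric vector of expressed fractions for outside /
#'   class1 / class2 (NA for empty categories).
#' @export
expressed_fraction <- function(assignment, tpm_matrix, cm, condition,
                               threshold = 5) {
  idx <- condition_samples(cm, condition)
  mean_tpm <- rowMeans(tpm_matrix[, idx, drop = FALSE])
  expressed <- mean_tpm >= threshold
  expressed <- expressed[assignment$gene_id]
  vapply(c("outside", "class1", "class2"), function(cat) {
    sel <- assignment$category == cat
    if (!any(sel)) NA_real_ else mean(expressed[sel])
  }, numeric(1))
}

#' Gene flow between two domain assignments
#'
#' Cross-tabulates the in-domain status (class1 or class2, collapsed) of
#' every gene between two cell states: `constitutive` (in domains in
#' both), `gained` (outside -> in), `lost` (in -> outside), `never`
#' (outside in both).
#'
#' @param assign_a,assign_b [assign_genes()] results over the same genes.
#' @return An object of class `flow_table`: list with `counts` (named
#'   vector), `crosstab` (3x3 category table) and `n_genes`.
#' @export
domain_flow <- function(assign_a, assign_b) {
  if (!setequal(assign_a$gene_id, assign_b$gene_id) ||
      nrow(assign_a) != nrow(assign_b))
    stop("assignments must cover the same gene universe")
  b <- assign_b[match(assign_a$gene_id, assign_b$gene_id), ]
  in_a <- assign_a$category != "outside"
  in_b <- b$category != "outside"
  counts <- c(constitutive = sum(in_a & in_b),
              gained = sum(!in_a & in_b),
              lost = sum(in_a & !in_b),
              never = sum(!in_a & !in_b))
  structure(list(counts = counts,
                 crosstab = table(from = assign_a$category, to = b$category),
                 n_genes = nrow(assign_a)),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("<flow_table> over", x$n_genes, "genes\n")
  print(x$counts)
  invisible(x)
}
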