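#' Classified domain set
#'
#' A sorted, non-overlapping set of genomic intervals, each labelled
#' `class1` (intermediate H3K9me2 density) or `class2` (high density),
#' held as a `GRanges` with a `class` metadata column.
#'
#' @param chrom,start,end Interval coordinates (1-based closed, as is
#'   conventional for `GRanges`; BED export converts to 0-based half-open).
#' @param class Character vector, each `"class1"` or `"class2"`.
#' @param layout A [genome_layout()] supplying the seqinfo.
#' @return A `GRanges` domain set.
#' @export
domain_set <- function(chrom, start, end, class, layout = NULL) {
  if (!all(class %in% c("class1", "class2")))
    stop("class must be 'class1' or 'class2'")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               class = as.character(class))
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  }
  as_domain_set(gr)
}

#' Validate and sort a GRanges as a domain set
#' @param gr A `GRanges` with a `class` metadata column.
#' @export
as_domain_set <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$class) || !all(gr$class %in% c("class1", "class2")))
    stop("domain set requires a 'class' column with values class1/class2")
  gr <- GenomicRanges::sort(gr)
  if (!GenomicRanges::isDisjoint(gr)) stop("domain intervals must not overlap")
  gr
}

#' Write a domain set as BED4 (name column = class)
#' @param domains A domain set `GRanges`.
#' @param path Output file.
#' @export
write_domain_bed <- function(domains, path) {
  gr <- domains
  gr$name <- gr$class
  gr$class <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED4 domain file (name column = class1/class2)
#' @param path BED file.
#' @param layout Optional [genome_layout()] for seqinfo.
#' @export
read_domain_bed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$class <- gr$name
  gr$name <- NULL
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  }
  as_domain_set(gr)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection bp over union bp after class-agnostic merging; the standard
#' measure of agreement between two domain calls.
#'
#' @param a,b `GRanges` objects (any metadata ignored).
#' @return A number in \[0, 1\] (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(granges_clean(a))
  b <- GenomicRanges::reduce(granges_clean(b))
  un <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (un == 0) return(1)
  sum(GenomicRanges::width(GenomicRanges::intersect(a, b))) / un
}

#' Strip metadata/strand from a GRanges
#' @keywords internal
granges_clean <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  gr
}
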