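#' Genome layout
#'
#' An ordered set of chromosome names and lengths. All binned tracks and
#' domain sets in a run share one layout.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp, all positive.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("`chrom` and `length` must have equal length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(list(chrom = chrom, length = setNames(length, chrom)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosome(s), ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Number of bins per chromosome for a layout at a given bin size
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return Named integer vector of bin counts (last bin may be partial).
#' @export
layout_n_bins <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"), bin_size > 0)
  setNames(as.integer(ceiling(layout$length / bin_size)), layout$chrom)
}

#' @rdname genome_layout
#' @param x A `genome_layout`.
#' @export
layout_seqinfo <- function(x) {
  GenomeInfoDb::Seqinfo(seqnames = x$chrom, seqlengths = as.integer(x$length))
}

#' Read / write a two-column chromosome sizes file
#'
#' Standard `<chrom>\t<length>` TSV as used by the UCSC tool chain.
#'
#' @param path File path.
#' @return For the reader, a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' @rdname read_chrom_sizes
#' @param layout A [genome_layout()] to write.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(data.frame(layout$chrom, as.integer(layout$length)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
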