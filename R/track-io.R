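#' Write a binned track as 4-column bedGraph
#'
#' Coordinates are 0-based half-open. Zero-valued bins are written
#' explicitly so that round trips are exact.
#'
#' @param track A [binned_track()].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  bs <- track$bin_size
  rows <- lapply(track$layout$chrom, function(ch) {
    v <- track$values[[ch]]
    start0 <- (seq_along(v) - 1) * bs
    end0 <- pmin(start0 + bs, track$layout$length[[ch]])
    data.frame(chrom = ch, start = start0, end = end0, value = v)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a binned track
#'
#' Uses the standard bedGraph parser, then places each record into the
#' fixed-bin grid of `layout` at `bin_size`. Records must align to the bin
#' grid; bins not covered by any record are 0, matching bedGraph gap
#' semantics.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @param condition,replicate,normalization Metadata for the track.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_size,
                          condition = NA_character_, replicate = NA_integer_,
                          normalization = "raw") {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) {
                   stop(sprintf("failed to parse bedGraph file '%s': %s",
                                path, conditionMessage(e)), call. = FALSE)
                 })
  nb <- layout_n_bins(layout, bin_size)
  vals <- lapply(layout$chrom, function(ch) numeric(nb[[ch]]))
  names(vals) <- layout$chrom
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   score = gr$score)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% layout$chrom)
      stop(sprintf("bedGraph file '%s' record %d: unknown chromosome '%s'",
                   path, i, ch))
    if (df$start0[i] %% bin_size != 0)
      stop(sprintf("bedGraph file '%s' record %d: interval not aligned to %d-bp bins",
                   path, i, as.integer(bin_size)))
    first <- df$start0[i] %/% bin_size + 1
    last <- ceiling(df$end[i] / bin_size)
    if (last > nb[[ch]])
      stop(sprintf("bedGraph file '%s' record %d: exceeds chromosome '%s'",
                   path, i, ch))
    vals[[ch]][first:last] <- df$score[i]
  }
  binned_track(layout, bin_size, vals, condition = condition,
               replicate = replicate, normalization = normalization)
}
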