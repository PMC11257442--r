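#' Binned coverage track
#'
#' Fixed-width binned signal over a genome layout. Values are nonnegative
#' reals; the last bin of each chromosome may cover a partial window. The
#' `normalization` field records provenance: `"raw"`, `"rpkm"`,
#' `"spikein_rpkm"` (after spike-in scaling) or `"averaged"` (replicate
#' mean). Missing-data bins are represented as 0, matching bedGraph gap
#' semantics.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @param values Named list (one element per chromosome, in layout order) of
#'   numeric vectors of per-bin values.
#' @param condition,replicate Optional labels carried in `meta`.
#' @param normalization Provenance string, default `"raw"`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(layout, bin_size, values,
                         condition = NA_character_, replicate = NA_integer_,
                         normalization = "raw") {
  stopifnot(inherits(layout, "genome_layout"))
  bin_size <- as.numeric(bin_size)
  if (bin_size <= 0) stop("bin_size must be positive")
  if (!identical(sort(names(values)), sort(layout$chrom)))
    stop("values must be a named list covering exactly the layout chromosomes")
  values <- values[layout$chrom]
  nb <- layout_n_bins(layout, bin_size)
  for (ch in layout$chrom) {
    v <- values[[ch]]
    if (length(v) != nb[[ch]])
      stop(sprintf("chromosome %s: expected %d bins, got %d", ch, nb[[ch]],
                   length(v)))
    if (any(!is.finite(v))) stop("track values must be finite")
    if (any(v < 0)) stop("track values must be nonnegative")
  }
  structure(list(layout = layout, bin_size = bin_size, values = values,
                 meta = list(condition = condition, replicate = replicate,
                             normalization = normalization)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("<binned_track> bin ", format(x$bin_size, big.mark = ","), " bp, ",
      sum(lengths(x$values)), " bins, normalization=", x$meta$normalization,
      "\n", sep = "")
  invisible(x)
}

#' Spike-in scale factor
#'
#' The per-library scale factor is an arbitrary constant (default 30,000)
#' divided by the number of properly paired reads aligned to the spike-in
#' genome, so deeper spike-in recovery yields a smaller factor.
#'
#' @param spike_reads Positive integer count of properly paired spike-in
#'   reads.
#' @param constant Numerator constant, default 30000.
#' @return An object of class `spikein_scale` with fields `constant`,
#'   `spike_reads` and `factor`.
#' @examples
#' compute_scale_factor(15000)$factor # 2
#' @export
compute_scale_factor <- function(spike_reads, constant = 30000) {
  if (length(spike_reads) != 1 || !is.finite(spike_reads) || spike_reads <= 0)
    stop("spike_reads must be a single positive number")
  if (constant <= 0) stop("constant must be positive")
  structure(list(constant = constant, spike_reads = spike_reads,
                 factor = constant / spike_reads),
            class = "spikein_scale")
}

#' Apply a spike-in scale factor to a track
#'
#' Multiplies every bin value by `scale$factor` and marks the track as
#' spike-in normalized. Applying a second spike-in scaling is an error.
#'
#' @param track A [binned_track()] with provenance `"raw"` or `"rpkm"`.
#' @param scale A [compute_scale_factor()] result.
#' @return The scaled track with provenance `"spikein_rpkm"`.
#' @export
normalize_track <- function(track, scale) {
  stopifnot(inherits(track, "binned_track"), inherits(scale, "spikein_scale"))
  if (!track$meta$normalization %in% c("raw", "rpkm"))
    stop("track is already normalized (", track$meta$normalization,
         "); refusing to scale twice")
  track$values <- lapply(track$values, function(v) v * scale$factor)
  track$meta$normalization <- "spikein_rpkm"
  track
}

#' Rebin a track to a coarser resolution
#'
#' Each target bin's value is the arithmetic mean of the source bins it
#' contains; a partial trailing window averages over the source bins that
#' exist (no zero padding).
#'
#' @param track A [binned_track()].
#' @param target_bin Target bin width, a positive integer multiple of the
#'   current bin size.
#' @return A [binned_track()] at the target resolution.
#' @export
rebin <- function(track, target_bin) {
  stopifnot(inherits(track, "binned_track"))
  k <- target_bin / track$bin_size
  if (target_bin <= 0 || abs(k - round(k)) > 1e-9)
    stop("target_bin must be a positive integer multiple of the bin size")
  k <- as.integer(round(k))
  if (k == 1L) return(track)
  vals <- lapply(track$values, function(v) {
    grp <- ceiling(seq_along(v) / k)
    as.numeric(tapply(v, grp, mean))
  })
  binned_track(track$layout, target_bin, vals,
               condition = track$meta$condition,
               replicate = track$meta$replicate,
               normalization = track$meta$normalization)
}

#' Average replicate tracks bin by bin
#'
#' @param tracks List of [binned_track()] objects sharing layout and bin
#'   size.
#' @return A [binned_track()] with provenance `"averaged"`.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) < 1) stop("need at least one track")
  ref <- tracks[[1]]
  for (t in tracks) {
    stopifnot(inherits(t, "binned_track"))
    if (t$bin_size != ref$bin_size ||
        !identical(t$layout$chrom, ref$layout$chrom) ||
        !identical(unname(t$layout$length), unname(ref$layout$length)))
      stop("tracks must share an identical layout and bin size")
  }
  vals <- lapply(ref$layout$chrom, function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)
  })
  names(vals) <- ref$layout$chrom
  conds <- unique(vapply(tracks, function(t) t$meta$condition, character(1)))
  binned_track(ref$layout, ref$bin_size, vals,
               condition = if (length(conds) == 1) conds else NA_character_,
               normalization = "averaged")
}

#' Midpoint positions of every bin as a GRanges
#' @keywords internal
.bin_midpoints <- function(track) {
  bs <- track$bin_size
  grl <- lapply(track$layout$chrom, function(ch) {
    n <- length(track$values[[ch]])
    chlen <- track$layout$length[[ch]]
    start0 <- (seq_len(n) - 1) * bs
    end <- pmin(start0 + bs, chlen)
    mid <- floor((start0 + end) / 2) + 1
    GenomicRanges::GRanges(ch, IRanges::IRanges(mid, mid))
  })
  gr <- unlist(GenomicRanges::GRangesList(grl))
  GenomeInfoDb::seqlevels(gr) <- track$layout$chrom
  gr
}

#' All values of a track as one vector (layout order)
#' @param track A [binned_track()].
#' @export
track_values <- function(track) unlist(track$values, use.names = FALSE)
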