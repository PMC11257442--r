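#' Domain statistics
#'
#' Per-class domain counts, total bp and length summaries, plus the median
#' contiguous domain length (class-agnostic, after coalescing abutting
#' domains) and the fraction of the assembled genome covered.
#'
#' @param domains A domain set `GRanges`.
#' @param layout A [genome_layout()].
#' @return An object of class `domain_stats`: list with `per_class`
#'   (data.frame), `median_contiguous_bp` (NA when the set is empty),
#'   `total_bp` and `coverage_fraction`.
#' @export
domain_stats <- function(domains, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ch <- as.character(GenomeInfoDb::seqnames(domains))
  if (length(domains)) {
    if (!all(ch %in% layout$chrom)) stop("domain on unknown chromosome")
    if (any(GenomicRanges::end(domains) > layout$length[ch]))
      stop("domain interval exceeds chromosome length")
  }
  per_class <- do.call(rbind, lapply(c("class1", "class2"), function(cl) {
    w <- GenomicRanges::width(domains[domains$class == cl])
    data.frame(class = cl, n = length(w), bp = sum(as.numeric(w)),
               min_bp = if (length(w)) min(w) else NA_real_,
               median_bp = if (length(w)) median(w) else NA_real_,
               max_bp = if (length(w)) max(w) else NA_real_)
  }))
  contig <- GenomicRanges::width(GenomicRanges::reduce(granges_clean(domains)))
  total_bp <- sum(as.numeric(GenomicRanges::width(domains)))
  structure(list(per_class = per_class,
                 median_contiguous_bp = if (length(contig)) median(contig)
                                        else NA_real_,
                 total_bp = total_bp,
                 coverage_fraction = total_bp / sum(layout$length)),
            class = "domain_stats")
}

#' @export
print.domain_stats <- function(x, ...) {
  print(x$per_class)
  cat(sprintf("coverage %.1f%% of genome; median contiguous length %s bp\n",
              100 * x$coverage_fraction,
              format(x$median_contiguous_bp, big.mark = ",")))
  invisible(x)
}

#' Cross-condition domain sharing
#'
#' Partitions the union of all conditions' domains by membership pattern
#' (which conditions contain each fragment). In `bp` mode every fragment
#' of the boundary-split union is assigned its exact membership; in
#' `domain` mode each class-agnostic union region counts as present in a
#' condition when some domain there reciprocally overlaps it by at least
#' `min_reciprocal`.
#'
#' @param domain_sets Named list (condition -> domain set `GRanges`), at
#'   least two conditions.
#' @param mode `"bp"` (default) or `"domain"`.
#' @param min_reciprocal Reciprocal-overlap threshold for `domain` mode,
#'   default 0.5.
#' @return An object of class `sharing_table`: list with `patterns`
#'   (data.frame of pattern, n, bp), `membership` (logical matrix),
#'   `shared_all_fraction` (bp in every condition / union bp), and
#'   `union_bp`.
#' @export
condition_sharing <- function(domain_sets, mode = c("bp", "domain"),
                              min_reciprocal = 0.5) {
  mode <- match.arg(mode)
  n <- length(domain_sets)
  if (n < 2) stop("need at least two conditions")
  nm <- names(domain_sets)
  if (is.null(nm) || any(nm == "")) stop("domain_sets must be named")
  clean <- lapply(domain_sets, granges_clean)
  if (mode == "bp") {
    frags <- GenomicRanges::disjoin(unlist(GenomicRanges::GRangesList(clean)))
  } else {
    frags <- GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(clean)))
  }
  memb <- matrix(FALSE, length(frags), n, dimnames = list(NULL, nm))
  for (i in seq_len(n)) {
    if (mode == "bp") {
      memb[, i] <- GenomicRanges::countOverlaps(frags, clean[[i]]) > 0
    } else {
      hit <- GenomicRanges::findOverlaps(frags, clean[[i]])
      if (length(hit)) {
        ov <- GenomicRanges::width(GenomicRanges::pintersect(
          frags[S4Vectors::queryHits(hit)],
          clean[[i]][S4Vectors::subjectHits(hit)]))
        rec <- pmin(ov / GenomicRanges::width(frags[S4Vectors::queryHits(hit)]),
                    ov / GenomicRanges::width(clean[[i]][S4Vectors::subjectHits(hit)]))
        ok <- unique(S4Vectors::queryHits(hit)[rec >= min_reciprocal])
        memb[ok, i] <- TRUE
      }
    }
  }
  w <- as.numeric(GenomicRanges::width(frags))
  pattern <- apply(memb, 1, function(z) paste(nm[z], collapse = "&"))
  patterns <- aggregate(cbind(bp = w, n = rep(1, length(w))),
                        by = list(pattern = pattern), FUN = sum)
  patterns <- patterns[order(-patterns$bp), ]
  shared_all <- sum(w[rowSums(memb) == n]) / sum(w)
  structure(list(patterns = patterns, membership = memb,
                 shared_all_fraction = shared_all, union_bp = sum(w),
                 mode = mode),
            class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("<sharing_table> mode=", x$mode, ", union ",
      format(x$union_bp, big.mark = ","), " bp, shared across all: ",
      sprintf("%.1f%%", 100 * x$shared_all_fraction), "\n", sep = "")
  print(utils::head(x$patterns, 10), row.names = FALSE)
  invisible(x)
}

#' Meta-domain signal profile
#'
#' Rescales each domain body to `body_bins` positions by linear
#' interpolation of the track bins whose midpoints fall inside the domain,
#' appends fixed-width flanks, and averages across domains -- the scaled
#' signal-over-regions profile familiar from deepTools computeMatrix.
#'
#' @param track A [binned_track()] (typically the replicate-averaged
#'   track).
#' @param domains A non-empty domain set `GRanges`.
#' @param body_bins Number of positions the body is rescaled to.
#' @param flank_bp Flank width in bp on each side.
#' @return Numeric vector of length `2 * flank_bp / bin_size + body_bins`,
#'   with a `section` attribute marking upstream/body/downstream.
#' @export
meta_domain_profile <- function(track, domains, body_bins = 100L,
                                flank_bp = 50000L) {
  stopifnot(inherits(track, "binned_track"))
  if (length(domains) == 0) stop("empty domain set")
  bs <- track$bin_size
  nf <- as.integer(round(flank_bp / bs))
  rows <- matrix(NA_real_, length(domains), 2L * nf + body_bins)
  ch_all <- as.character(GenomeInfoDb::seqnames(domains))
  for (i in seq_along(domains)) {
    ch <- ch_all[i]
    v <- track$values[[ch]]
    if (is.null(v)) stop("domain on chromosome absent from track")
    # bins whose midpoint lies inside the domain body
    s0 <- GenomicRanges::start(domains)[i] - 1
    e0 <- GenomicRanges::end(domains)[i]
    mid <- (seq_along(v) - 1) * bs + bs / 2
    inside <- which(mid >= s0 & mid < e0)
    if (length(inside) == 0)
      inside <- max(1L, min(length(v), as.integer(s0 %/% bs) + 1L))
    body <- v[inside]
    body_r <- if (length(body) == 1) rep(body, body_bins) else
      approx(seq_along(body), body, n = body_bins)$y
    left_idx <- (min(inside) - nf):(min(inside) - 1)
    right_idx <- (max(inside) + 1):(max(inside) + nf)
    left <- ifelse(left_idx >= 1, v[pmax(left_idx, 1)], NA_real_)
    right <- ifelse(right_idx <= length(v), v[pmin(right_idx, length(v))],
                    NA_real_)
    if (nf > 0) rows[i, ] <- c(left, body_r, right) else rows[i, ] <- body_r
  }
  prof <- colMeans(rows, na.rm = TRUE)
  attr(prof, "section") <- c(rep("upstream", nf), rep("body", body_bins),
                             rep("downstream", nf))
  prof
}

#' Mean and dispersion of track signal within regions
#'
#' Selects every bin whose midpoint lies inside the region set (or all
#' bins, when `regions` is `NULL`) and returns the mean and the population
#' standard deviation of the selected values.
#'
#' @param track A [binned_track()].
#' @param regions A `GRanges` (class column ignored) or `NULL` for the
#'   whole genome.
#' @return List with `mean`, `sd` and `n_bins`.
#' @export
signal_dispersion <- function(track, regions = NULL) {
  stopifnot(inherits(track, "binned_track"))
  if (is.null(regions)) {
    x <- track_values(track)
  } else {
    if (length(regions) == 0) stop("regions must be non-empty (or NULL)")
    mids <- .bin_midpoints(track)
    sel <- GenomicRanges::countOverlaps(mids, granges_clean(regions)) > 0
    x <- track_values(track)[sel]
  }
  if (length(x) == 0) return(list(mean = NA_real_, sd = NA_real_, n_bins = 0L))
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)), n_bins = length(x))
}

#' Write a sharing table's membership matrix as an UpSet-ready TSV
#' @param sharing A [condition_sharing()] result.
#' @param path Output file.
#' @export
write_sharing_table <- function(sharing, path) {
  utils::write.table(sharing$patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
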