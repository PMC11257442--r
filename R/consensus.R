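#' Multi-way intersection of replicate domain calls
#'
#' Partitions the union of all replicate domains at every interval
#' boundary; each resulting fragment records which replicates cover it and
#' with which class (the multi-intersect operation familiar from bedtools).
#'
#' @param replicate_domains List of domain set `GRanges` (one per
#'   replicate), each internally non-overlapping.
#' @return An object of class `support_partition` with fields `fragments`
#'   (disjoint `GRanges` covering the union), `presence` (fragments x
#'   replicates logical matrix), `classes` (same shape, character),
#'   `support` (integer vector) and `n_replicates`.
#' @export
multi_intersect <- function(replicate_domains) {
  n <- length(replicate_domains)
  if (n < 1) stop("need at least one replicate domain set")
  for (d in replicate_domains) {
    if (!GenomicRanges::isDisjoint(d))
      stop("overlapping intervals within one replicate are not allowed")
  }
  all_gr <- unlist(GenomicRanges::GRangesList(
    lapply(replicate_domains, granges_clean)))
  frags <- GenomicRanges::disjoin(all_gr)
  pres <- matrix(FALSE, length(frags), n)
  cls <- matrix(NA_character_, length(frags), n)
  for (i in seq_len(n)) {
    hit <- GenomicRanges::findOverlaps(frags, replicate_domains[[i]])
    pres[S4Vectors::queryHits(hit), i] <- TRUE
    cls[S4Vectors::queryHits(hit), i] <-
      as.character(replicate_domains[[i]]$class[S4Vectors::subjectHits(hit)])
  }
  structure(list(fragments = frags, presence = pres, classes = cls,
                 support = rowSums(pres), n_replicates = n),
            class = "support_partition")
}

#' @export
print.support_partition <- function(x, ...) {
  cat("<support_partition> ", length(x$fragments), " fragment(s) over ",
      x$n_replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

#' Consensus domains from a support partition
#'
#' Keeps fragments covered by at least `min_support` replicates. The class
#' of each kept fragment is the majority class among its supporting
#' replicates, with ties resolved conservatively to `class1`; adjacent
#' same-class fragments are coalesced. `min_support = 1` yields the union
#' of the replicate calls, `min_support = n` their intersection.
#'
#' @param partition A [multi_intersect()] result.
#' @param min_support Required replicate support, between 1 and the number
#'   of replicates. Default 2 (majority of three replicates).
#' @return A domain set `GRanges`.
#' @export
consensus_filter <- function(partition, min_support = 2L) {
  stopifnot(inherits(partition, "support_partition"))
  if (min_support < 1 || min_support > partition$n_replicates)
    stop("min_support must be between 1 and the number of replicates")
  keep <- partition$support >= min_support
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges(class = character(0))
    return(as_domain_set(gr))
  }
  frags <- partition$fragments[keep]
  cls <- partition$classes[keep, , drop = FALSE]
  n2 <- rowSums(cls == "class2", na.rm = TRUE)
  n1 <- rowSums(cls == "class1", na.rm = TRUE)
  frag_class <- ifelse(n2 > n1, "class2", "class1")
  out <- lapply(c("class1", "class2"), function(cl) {
    sub <- frags[frag_class == cl]
    if (length(sub) == 0) return(GenomicRanges::GRanges(class = character(0)))
    red <- GenomicRanges::reduce(sub)
    red$class <- cl
    red
  })
  gr <- unlist(GenomicRanges::GRangesList(out))
  as_domain_set(gr)
}

#' Write a support partition as a TSV table
#' @param partition A [multi_intersect()] result.
#' @param path Output file.
#' @export
write_support_table <- function(partition, path) {
  tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(partition$fragments)),
    start = GenomicRanges::start(partition$fragments) - 1,
    end = GenomicRanges::end(partition$fragments),
    support = partition$support)
  for (i in seq_len(partition$n_replicates)) {
    tab[[paste0("rep", i)]] <- ifelse(partition$presence[, i],
                                      partition$classes[, i], ".")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
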