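# Independent oracles and small builders shared across the test files.

# Exhaustive HMM likelihood: sum over all K^T hidden paths.
enum_loglik <- function(model, x) {
  K <- length(model$means)
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- model$initial[s[1]] * dnorm(x[1], model$means[s[1]], model$sds[s[1]])
    if (Tn > 1) {
      for (t in 2:Tn) {
        p <- p * model$transition[s[t - 1], s[t]] *
          dnorm(x[t], model$means[s[t]], model$sds[s[t]])
      }
    }
    total <- total + p
  }
  log(total)
}

# Exhaustive Viterbi: the highest-probability path by enumeration.
enum_viterbi <- function(model, x) {
  K <- length(model$means)
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    lp <- log(model$initial[s[1]]) +
      dnorm(x[1], model$means[s[1]], model$sds[s[1]], log = TRUE)
    if (Tn > 1) {
      for (t in 2:Tn) {
        lp <- lp + log(model$transition[s[t - 1], s[t]]) +
          dnorm(x[t], model$means[s[t]], model$sds[s[t]], log = TRUE)
      }
    }
    if (lp > best) {
      best <- lp
      best_path <- s
    }
  }
  best_path
}

# Random valid HMM with K states.
random_model <- function(K, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K, 0.05, 1), K, K)
  A <- A / rowSums(A)
  p <- runif(K, 0.05, 1)
  list(initial = p / sum(p), transition = A,
       means = sort(rnorm(K, 0, 3)), sds = runif(K, 0.3, 1.5))
}

# Single-chromosome layout/track builders.
make_layout <- function(lengths, chroms = paste0("chr", seq_along(lengths))) {
  genome_layout(chroms, lengths)
}

make_track <- function(values, bin_size = 1000, chrom_length = NULL, ...) {
  if (!is.list(values)) values <- list(chr1 = values)
  if (is.null(chrom_length))
    chrom_length <- vapply(values, length, numeric(1)) * bin_size
  layout <- genome_layout(names(values), chrom_length)
  binned_track(layout, bin_size, values, ...)
}

# Brute-force per-bp replicate support over a single chromosome.
bp_support <- function(replicate_domains, chrom_len) {
  cov <- matrix(0L, chrom_len, length(replicate_domains))
  for (i in seq_along(replicate_domains)) {
    d <- replicate_domains[[i]]
    for (j in seq_along(d)) {
      cov[GenomicRanges::start(d)[j]:GenomicRanges::end(d)[j], i] <- 1L
    }
  }
  rowSums(cov)
}

# Random non-overlapping domain set on one chromosome.
random_domains <- function(chrom_len, n, layout, seed) {
  set.seed(seed)
  bounds <- sort(sample.int(chrom_len - 1, 2 * n))
  starts <- bounds[seq(1, 2 * n, by = 2)]
  ends <- bounds[seq(2, 2 * n, by = 2)]
  keep <- ends > starts
  domain_set("chr1", starts[keep] + 1, ends[keep],
             sample(c("class1", "class2"), sum(keep), replace = TRUE),
             layout)
}
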