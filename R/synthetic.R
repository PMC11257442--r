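#' Synthetic study configuration
#'
#' Parameters of the synthetic genome, planted H3K9me2 domain map, coverage
#' emission model, and expression effects. The defaults describe the
#' conditions the package's validation suite runs under: a 500-Mb
#' five-chromosome genome at 10-kb bins (50,000 bins), three CUT&RUN
#' replicates, a sticky four-state emission model with ordered means on the
#' log1p scale, ~60% of the genome in domains, strong repression of
#' domain-resident genes in the tethered ("wild-type") condition, and a
#' marked subset of TE copies induced at least ten-fold in the displaced
#' ("mutant") condition.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param bin_size_bp Bin width of simulated tracks (default 10 kb).
#' @param target_domain_fraction Fraction of the genome planted inside
#'   class1+class2 domains.
#' @param class2_share Fraction of domain bp that is class2.
#' @param blacklist_fraction Fraction of bins planted as short, isolated
#'   artifact runs with extreme signal.
#' @param emission_means,emission_sds Per-state Gaussian emission
#'   parameters on the log1p scale, ordered background < class1 < class2 <
#'   blacklist.
#' @param stickiness Self-transition probability of the domain-state
#'   Markov chain.
#' @param n_replicates CUT&RUN replicates per condition.
#' @param replicate_noise_sd Extra per-bin replicate noise on the
#'   transformed scale.
#' @param spike_read_counts Per-replicate spike-in read counts; library
#'   depth is proportional to these, so spike-in scaling is required to
#'   put replicates on a common scale.
#' @param n_genes,n_te_copies Feature counts.
#' @param te_derepressed_fraction Fraction of TE copies marked as
#'   derepressible (planted inside class2 domains).
#' @param repression_effect Multiplicative expression reduction applied to
#'   class2-resident features in the wild-type condition (class1 residents
#'   get the geometric midpoint, `sqrt(repression_effect)`).
#' @param derepression_fold Minimum planted induction of marked TE copies
#'   in the mutant condition.
#' @param derepression_fold_spread Exponent range of the per-copy
#'   induction spread: each marked copy's fold is
#'   `derepression_fold^(1 + runif(0, spread))`, emulating a population of
#'   copies induced *at least* `derepression_fold`-fold. Set 0 for a
#'   uniform planted fold.
#' @param n_rna_replicates RNA-seq replicates per condition.
#' @param nb_dispersion Negative-binomial size parameter of simulated
#'   counts.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chromosomes = 5L,
                         chrom_length_bp = 1e8,
                         bin_size_bp = 1e4,
                         target_domain_fraction = 0.60,
                         class2_share = 0.40,
                         blacklist_fraction = 0.005,
                         emission_means = c(1, 2.5, 4.5, 8),
                         emission_sds = c(0.5, 0.5, 0.5, 0.5),
                         stickiness = 0.99,
                         n_replicates = 3L,
                         replicate_noise_sd = 0.1,
                         spike_read_counts = c(15000L, 20000L, 30000L),
                         n_genes = 2000L,
                         n_te_copies = 1000L,
                         te_derepressed_fraction = 0.10,
                         repression_effect = 0.10,
                         derepression_fold = 10,
                         derepression_fold_spread = 1.5,
                         n_rna_replicates = 4L,
                         nb_dispersion = 20) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, bin_size_bp = bin_size_bp,
              target_domain_fraction = target_domain_fraction,
              class2_share = class2_share,
              blacklist_fraction = blacklist_fraction,
              emission_means = emission_means, emission_sds = emission_sds,
              stickiness = stickiness, n_replicates = as.integer(n_replicates),
              replicate_noise_sd = replicate_noise_sd,
              spike_read_counts = as.integer(spike_read_counts),
              n_genes = as.integer(n_genes),
              n_te_copies = as.integer(n_te_copies),
              te_derepressed_fraction = te_derepressed_fraction,
              repression_effect = repression_effect,
              derepression_fold = derepression_fold,
              derepression_fold_spread = derepression_fold_spread,
              n_rna_replicates = as.integer(n_rna_replicates),
              nb_dispersion = nb_dispersion)
  if (cfg$n_chromosomes < 1 || cfg$chrom_length_bp <= 0 || cfg$bin_size_bp <= 0 ||
      cfg$n_replicates < 1 || cfg$n_rna_replicates < 1 ||
      cfg$n_genes < 0 || cfg$n_te_copies < 0)
    stop("non-positive lengths or counts in configuration")
  fr <- c(cfg$target_domain_fraction, cfg$class2_share,
          cfg$blacklist_fraction, cfg$te_derepressed_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$stickiness <= 0 || cfg$stickiness >= 1)
    stop("stickiness must lie strictly between 0 and 1")
  if (length(cfg$emission_means) != 4 || any(diff(cfg$emission_means) <= 0))
    stop("emission_means must be a strictly increasing 4-vector")
  if (length(cfg$emission_sds) != 4 || any(cfg$emission_sds <= 0))
    stop("emission_sds must be a positive 4-vector")
  if (any(cfg$spike_read_counts <= 0))
    stop("spike_read_counts must be positive")
  if (cfg$repression_effect <= 0 || cfg$derepression_fold <= 0)
    stop("effects must be positive")
  structure(cfg, class = "synth_config")
}

# State codes used throughout the generator
.ST_BG <- 1L; .ST_C1 <- 2L; .ST_C2 <- 3L; .ST_BL <- 4L

#' Generate planted ground truth
#'
#' Samples a contiguous-run domain map per chromosome from a two-block
#' sticky Markov chain (domain runs leave with rate `1 - stickiness`;
#' background runs leave at the rate that makes the stationary domain
#' fraction equal the target), assigns each domain run class1 or class2,
#' plants short isolated blacklist runs inside background, then flips whole
#' runs until the realized domain fraction is within 0.5% of the target.
#' Genes and TE copies are placed on the map, expression means are drawn,
#' and a marked TE subset (inside class2) receives its planted induction
#' folds.
#'
#' @param config A [synth_config()].
#' @return An object of class `synthetic_truth`: list with `config`,
#'   `layout`, `states` (per-condition list of per-chromosome planted
#'   state vectors; codes 1=background, 2=class1, 3=class2, 4=blacklist),
#'   `domains` (planted domain set `GRanges`), `genes` and `te`
#'   (data.frames with planted means), and `emission`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  layout <- genome_layout(paste0("chr", seq_len(config$n_chromosomes)),
                          rep(config$chrom_length_bp, config$n_chromosomes))
  nb <- layout_n_bins(layout, config$bin_size_bp)
  q_dom <- 1 - config$stickiness
  tf <- config$target_domain_fraction
  q_bg <- if (tf >= 1) 1 else if (tf <= 0) 0 else q_dom * tf / (1 - tf)

  states <- lapply(layout$chrom, function(ch) {
    n <- nb[[ch]]
    s <- integer(0)
    in_dom <- runif(1) < tf
    while (length(s) < n) {
      if (tf <= 0) in_dom <- FALSE
      if (tf >= 1) in_dom <- TRUE
      len <- if (in_dom) rgeom(1, q_dom) + 1 else
        if (q_bg <= 0) n else rgeom(1, q_bg) + 1
      st <- if (in_dom) {
        if (runif(1) < config$class2_share) .ST_C2 else .ST_C1
      } else .ST_BG
      s <- c(s, rep(st, len))
      in_dom <- !in_dom
    }
    s[seq_len(n)]
  })
  names(states) <- layout$chrom

  # plant isolated short blacklist runs inside background
  n_total <- sum(nb)
  n_bl <- round(config$blacklist_fraction * n_total)
  while (n_bl > 0) {
    ch <- sample(layout$chrom, 1, prob = nb / sum(nb))
    len <- sample(1:3, 1)
    pos <- sample.int(max(nb[[ch]] - len, 1), 1)
    idx <- pos:(pos + len - 1)
    if (all(states[[ch]][idx] == .ST_BG)) {
      states[[ch]][idx] <- .ST_BL
      n_bl <- n_bl - len
    }
  }

  states <- .adjust_domain_fraction(states, config)

  domains <- .states_to_domains(states, layout, config$bin_size_bp)
  genes <- .place_genes(config, layout, domains)
  te <- .place_te_copies(config, layout, states, domains)

  structure(list(config = config, layout = layout,
                 states = list(`wild-type` = states, mutant = states),
                 domains = domains, genes = genes, te = te,
                 emission = list(means = config$emission_means,
                                 sds = config$emission_sds,
                                 stickiness = config$stickiness),
                 conditions = c("wild-type", "mutant")),
            class = "synthetic_truth")
}

#' @keywords internal
.adjust_domain_fraction <- function(states, config) {
  tf <- config$target_domain_fraction
  n_total <- sum(lengths(states))
  realized <- function() sum(vapply(states, function(s)
    sum(s == .ST_C1 | s == .ST_C2), numeric(1))) / n_total
  for (iter in seq_len(5000)) {
    dev <- realized() - tf
    need <- round(abs(dev) * n_total)
    if (need < max(1, 0.002 * n_total)) break
    ch <- sample(names(states), 1, prob = lengths(states))
    s <- states[[ch]]
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    if (dev < 0) {
      cand <- which(r$values == .ST_BG & r$lengths <= max(need, 2))
      if (!length(cand)) next
      k <- cand[sample.int(length(cand), 1)]
      newst <- if (runif(1) < config$class2_share) .ST_C2 else .ST_C1
    } else {
      cand <- which(r$values %in% c(.ST_C1, .ST_C2) &
                    r$lengths <= max(need, 2))
      if (!length(cand)) next
      k <- cand[sample.int(length(cand), 1)]
      newst <- .ST_BG
    }
    s[starts[k]:ends[k]] <- newst
    states[[ch]] <- s
  }
  states
}

#' @keywords internal
.states_to_domains <- function(states, layout, bin_size) {
  out <- list()
  for (ch in names(states)) {
    r <- rle(states[[ch]])
    ends_bin <- cumsum(r$lengths); starts_bin <- ends_bin - r$lengths + 1
    keep <- r$values %in% c(.ST_C1, .ST_C2)
    if (!any(keep)) next
    out[[ch]] <- GenomicRanges::GRanges(
      ch,
      IRanges::IRanges((starts_bin[keep] - 1) * bin_size + 1,
                       pmin(ends_bin[keep] * bin_size,
                            layout$length[[ch]])),
      class = ifelse(r$values[keep] == .ST_C2, "class2", "class1"))
  }
  gr <- if (length(out)) unlist(GenomicRanges::GRangesList(out),
                                use.names = FALSE)
        else GenomicRanges::GRanges(class = character(0))
  GenomeInfoDb::seqlevels(gr) <- layout$chrom
  GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  as_domain_set(gr)
}

#' @keywords internal
.place_genes <- function(config, layout, domains) {
  n <- config$n_genes
  if (n == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), effective_length = numeric(0),
                      category = character(0), base_mean = numeric(0),
                      mu_wt = numeric(0), mu_mut = numeric(0)))
  chrom <- sample(layout$chrom, n, replace = TRUE,
                  prob = layout$length / sum(layout$length))
  len <- round(exp(runif(n, log(2e3), log(5e4))))
  len <- pmin(len, floor(layout$length[chrom] / 4))
  start <- floor(runif(n, 1, layout$length[chrom] - len))
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                      chrom = chrom, start = start, end = start + len - 1,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      effective_length = len, stringsAsFactors = FALSE)
  assign <- assign_genes(genes, domains)
  genes$category <- as.character(assign$category)
  # wide lognormal spread so that the expressed threshold bisects the
  # population, as in real transcriptomes
  genes$base_mean <- rlnorm(n, log(100), 2)
  eff <- c(outside = 1,
           class1 = sqrt(config$repression_effect),
           class2 = config$repression_effect)
  genes$mu_wt <- genes$base_mean * eff[genes$category]
  genes$mu_mut <- genes$base_mean
  genes
}

#' @keywords internal
.place_te_copies <- function(config, layout, states, domains) {
  n <- config$n_te_copies
  empty <- data.frame(copy_id = character(0), family = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      category = character(0), derepressed = logical(0),
                      planted_fold = numeric(0), base_mean = numeric(0),
                      mu_wt = numeric(0), mu_mut = numeric(0),
                      k9_mean = numeric(0))
  if (n == 0) return(empty)
  n_marked <- round(n * config$te_derepressed_fraction)
  bs <- config$bin_size_bp

  c2 <- domains[domains$class == "class2"]
  if (n_marked > 0 && length(c2) == 0)
    stop("cannot plant derepressed copies: no class2 domains")

  len <- round(runif(n, 1000, pmin(6000, config$chrom_length_bp / 10)))
  chrom <- character(n); start <- numeric(n)
  marked <- c(rep(TRUE, n_marked), rep(FALSE, n - n_marked))
  if (n_marked > 0) {
    host_ok <- GenomicRanges::width(c2) > max(len) + 2
    hosts <- c2[host_ok]
    if (length(hosts) == 0) stop("class2 domains too short to host TE copies")
    pick <- sample.int(length(hosts), n_marked, replace = TRUE,
                       prob = as.numeric(GenomicRanges::width(hosts)))
    for (i in seq_len(n_marked)) {
      h <- hosts[pick[i]]
      s0 <- GenomicRanges::start(h)
      e0 <- GenomicRanges::end(h) - len[i]
      chrom[i] <- as.character(GenomeInfoDb::seqnames(h))
      start[i] <- floor(runif(1, s0, e0))
    }
  }
  if (n - n_marked > 0) {
    idx <- which(!marked)
    chrom[idx] <- sample(layout$chrom, length(idx), replace = TRUE,
                         prob = layout$length / sum(layout$length))
    start[idx] <- floor(runif(length(idx), 1,
                              layout$length[chrom[idx]] - len[idx]))
  }
  family <- character(n)
  family[marked] <- "L1MdA_I"
  family[!marked] <- sample(c("L1MdA_I", "L1MdF_II", "ERVK10C", "B2_Mm1a"),
                            n - n_marked, replace = TRUE,
                            prob = c(0.4, 0.2, 0.2, 0.2))
  te <- data.frame(copy_id = sprintf("te%05d", seq_len(n)), family = family,
                   chrom = chrom, start = start, end = start + len - 1,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  # category of each copy from the planted state at its midpoint
  mid_bin <- pmax(1, ceiling(((te$start + te$end) / 2) / bs))
  state_at <- mapply(function(ch, b) states[[ch]][min(b, length(states[[ch]]))],
                     te$chrom, mid_bin)
  te$category <- c("outside", "class1", "class2", "outside")[state_at]
  te$derepressed <- marked
  spread <- config$derepression_fold_spread
  te$planted_fold <- ifelse(marked,
                            config$derepression_fold^(1 + runif(n, 0, spread)),
                            1)
  te$base_mean <- rlnorm(n, log(120), 0.5)
  eff <- c(outside = 1,
           class1 = sqrt(config$repression_effect),
           class2 = config$repression_effect)
  te$mu_wt <- te$base_mean * eff[te$category]
  te$mu_mut <- te$mu_wt * te$planted_fold
  k9_levels <- c(5, 25, 80, 120)
  te$k9_mean <- k9_levels[state_at]
  te
}

#' Simulate spike-in-controlled coverage tracks
#'
#' Per replicate and bin, a transformed value is drawn as
#' `Normal(mean[state], sd[state]) + Normal(0, replicate_noise_sd)`,
#' inverse-transformed with `expm1` and clipped at 0. Library depth is
#' proportional to the replicate's spike-in read count (raw values are
#' multiplied by `spike_reads / spike_constant`), so applying
#' [compute_scale_factor()] and [normalize_track()] restores the planted
#' emission scale.
#'
#' @param truth A [generate_truth()] result.
#' @param condition One of the truth's condition labels.
#' @param spike_constant Constant used to model depth, default 30000.
#' @return List of length `n_replicates`; each element is a list with
#'   `track` (a raw [binned_track()]) and `spike_reads`.
#' @export
simulate_tracks <- function(truth, condition, spike_constant = 30000) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!condition %in% truth$conditions)
    stop("unknown condition '", condition, "'")
  cfg <- truth$config
  states <- truth$states[[condition]]
  cond_offset <- 1000L * match(condition, truth$conditions)
  spikes <- rep_len(cfg$spike_read_counts, cfg$n_replicates)
  lapply(seq_len(cfg$n_replicates), function(j) {
    set.seed(cfg$seed + cond_offset + j)
    depth <- spikes[j] / spike_constant
    vals <- lapply(states, function(s) {
      y <- rnorm(length(s), cfg$emission_means[s], cfg$emission_sds[s]) +
        rnorm(length(s), 0, cfg$replicate_noise_sd)
      pmax(expm1(y), 0) * depth
    })
    list(track = binned_track(truth$layout, cfg$bin_size_bp, vals,
                              condition = condition, replicate = j,
                              normalization = "raw"),
         spike_reads = spikes[j])
  })
}

#' Simulate RNA-seq count tables for genes and TE copies
#'
#' Negative-binomial counts with the planted per-condition means; optional
#' per-sample depth multipliers emulate unequal library sizes (for
#' size-factor recovery checks). Samples are ordered wild-type replicates
#' then mutant replicates.
#'
#' @param truth A [generate_truth()] result.
#' @param depth Optional numeric vector of per-sample depth multipliers,
#'   length `2 * n_rna_replicates` (default all 1).
#' @return List with `genes` and `te`, both [counts_matrix()] objects.
#' @export
simulate_counts <- function(truth, depth = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  nrep <- cfg$n_rna_replicates
  n_samp <- 2L * nrep
  if (is.null(depth)) depth <- rep(1, n_samp)
  if (length(depth) != n_samp) stop("depth must have one entry per sample")
  cond <- rep(c("wild-type", "mutant"), each = nrep)
  set.seed(cfg$seed + 5000L)
  draw <- function(feats, id_col) {
    mu <- cbind(matrix(feats$mu_wt, nrow(feats), nrep),
                matrix(feats$mu_mut, nrow(feats), nrep))
    mu <- sweep(mu, 2, depth, `*`)
    mat <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                  nrow(feats), n_samp)
    rownames(mat) <- feats[[id_col]]
    colnames(mat) <- paste0(rep(c("wt", "mut"), each = nrep), "_r",
                            rep(seq_len(nrep), 2))
    counts_matrix(mat, cond)
  }
  list(genes = draw(truth$genes, "gene_id"),
       te = draw(truth$te, "copy_id"))
}

#' Simulate H3K9me2 CUT&RUN counts on TE copies
#'
#' Negative-binomial counts whose means follow the planted chromatin state
#' at each copy (background low, class1 intermediate, class2 high).
#'
#' @param truth A [generate_truth()] result.
#' @param condition Condition label (H3K9me2 is planted identically across
#'   conditions, matching preserved deposition).
#' @return A [counts_matrix()] with `n_replicates` samples.
#' @export
simulate_te_k9_counts <- function(truth, condition = "wild-type") {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  set.seed(cfg$seed + 7000L + match(condition, truth$conditions))
  nrep <- cfg$n_replicates
  mu <- matrix(truth$te$k9_mean, nrow(truth$te), nrep)
  mat <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                nrow(truth$te), nrep)
  rownames(mat) <- truth$te$copy_id
  colnames(mat) <- paste0(condition, "_k9_r", seq_len(nrep))
  counts_matrix(mat, rep(condition, nrep))
}

#' Write a truth manifest as JSON
#' @param truth A [generate_truth()] result.
#' @param path Output file.
#' @export
write_truth_manifest <- function(truth, path) {
  realized <- sum(vapply(truth$states[[1]], function(s)
    sum(s == .ST_C1 | s == .ST_C2), numeric(1))) /
    sum(lengths(truth$states[[1]]))
  jsonlite::write_json(
    list(config = unclass(truth$config),
         realized_domain_fraction = realized,
         n_domains = length(truth$domains),
         n_genes = nrow(truth$genes), n_te_copies = nrow(truth$te),
         n_derepressed = sum(truth$te$derepressed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Realized planted domain fraction of a truth object
#' @param truth A [generate_truth()] result.
#' @param condition Condition label, default the first.
#' @export
realized_domain_fraction <- function(truth, condition = truth$conditions[1]) {
  s <- truth$states[[condition]]
  sum(vapply(s, function(x) sum(x == .ST_C1 | x == .ST_C2), numeric(1))) /
    sum(lengths(s))
}
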