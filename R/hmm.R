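#' Fit a Gaussian hidden Markov model to a binned track
#'
#' Baum-Welch maximum-likelihood fit of a `n_states`-state HMM with
#' univariate Gaussian emissions on log1p-transformed bin values. Each
#' chromosome is treated as an independent observation sequence. Emission
#' means are initialized at signal percentiles (20/50/80/99.5 for the
#' default four states) with a sticky transition prior; `n_restarts`
#' restarts jitter the initial means with a seeded perturbation and the fit
#' with the best final log-likelihood is returned.
#'
#' @param track A [binned_track()] at the analysis bin size (10 kb in the
#'   reference workflow).
#' @param n_states Number of hidden states, default 4 (background, class 1,
#'   class 2, blacklist).
#' @param seed Integer seed controlling restart jitter.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @param n_restarts Number of seeded restarts.
#' @param sd_floor Lower bound on emission standard deviations, preventing
#'   collapse onto repeated values.
#' @param self_prior Initial self-transition probability.
#' @return An object of class `hmm_model` with fields `initial`,
#'   `transition`, `means`, `sds`, `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `bin_size`, and `transform`.
#' @export
fit_hmm <- function(track, n_states = 4L, seed = 1L, max_iter = 100L,
                    tol = 1e-6, n_restarts = 3L, sd_floor = 1e-3,
                    self_prior = 0.95) {
  stopifnot(inherits(track, "binned_track"), n_states >= 1)
  obs <- lapply(track$values, log1p)
  allx <- unlist(obs, use.names = FALSE)
  if (length(unique(allx)) < n_states)
    stop("degenerate input: fewer distinct transformed values than states")

  # the top state anchors the rare very-high-artifact component, so its
  # init must sit deep in the upper tail rather than at the class2 boundary
  probs <- if (n_states == 4) c(0.20, 0.50, 0.80, 0.9995)
           else seq(0.15, 0.95, length.out = n_states)
  mu0 <- as.numeric(quantile(allx, probs, names = FALSE))
  # nudge apart any coincident percentile inits
  eps <- max(diff(range(allx)) * 1e-3, 1e-6)
  mu0 <- mu0 + (seq_len(n_states) - 1) * eps * (diff(mu0[c(1, n_states)]) == 0)
  for (k in seq_len(n_states)[-1])
    if (mu0[k] <= mu0[k - 1]) mu0[k] <- mu0[k - 1] + eps
  sd0 <- max(sd(allx) / n_states, sd_floor * 10)

  # subsample for k-means-based restarts; percentile init anchors the first
  xs <- if (length(allx) > 20000) {
    set.seed(as.integer(seed))
    sample(allx, 20000)
  } else allx
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    mu <- if (r == 1) {
      mu0
    } else {
      km <- tryCatch(
        sort(as.numeric(stats::kmeans(xs, centers = n_states,
                                      nstart = 3)$centers)),
        error = function(e) mu0)
      sort(km + rnorm(n_states, 0, 0.05 * diff(range(allx)) / n_states))
    }
    fit <- .baum_welch(obs, mu, rep(sd0, n_states), n_states, max_iter, tol,
                       sd_floor, self_prior)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$bin_size <- track$bin_size
  best$transform <- "log1p"
  class(best) <- "hmm_model"
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  best
}

#' @keywords internal
.baum_welch <- function(obs, mu, sdv, K, max_iter, tol, sd_floor, self_prior) {
  A <- matrix((1 - self_prior) / max(K - 1, 1), K, K)
  diag(A) <- if (K == 1) 1 else self_prior
  pi0 <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    E <- lapply(obs, function(x) {
      sd_ <- .shifted_dens(x, mu, sdv)
      fb <- hmm_fb_cpp(sd_$dens, A, pi0)
      fb$loglik <- fb$loglik + sd_$shift
      fb$x <- x
      fb
    })
    ll <- sum(vapply(E, function(e) e$loglik, numeric(1)))
    if (length(ll_trace) && ll < ll_prev - 1e-8 * (1 + abs(ll_prev)))
      warning("Baum-Welch log-likelihood decreased")
    ll_trace <- c(ll_trace, ll)

    g1 <- Reduce(`+`, lapply(E, function(e) e$gamma[1, , drop = TRUE]))
    pi0 <- g1 / sum(g1)
    xi <- Reduce(`+`, lapply(E, function(e) e$xi_sum))
    rs <- rowSums(xi)
    A <- xi / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K

    den <- Reduce(`+`, lapply(E, function(e) colSums(e$gamma)))
    num <- Reduce(`+`, lapply(E, function(e) colSums(e$gamma * e$x)))
    occupied <- den > 1e-8
    mu_new <- ifelse(occupied, num / ifelse(occupied, den, 1), mu)
    v <- Reduce(`+`, lapply(E, function(e) {
      vapply(seq_len(K), function(k)
        sum(e$gamma[, k] * (e$x - mu_new[k])^2), numeric(1))
    }))
    sd_new <- ifelse(occupied, sqrt(v / ifelse(occupied, den, 1)), sdv)
    mu <- mu_new
    sdv <- pmax(sd_new, sd_floor)

    if (it > 1 && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  list(n_states = K, initial = pi0, transition = A, means = mu, sds = sdv,
       loglik = ll_prev, loglik_trace = ll_trace, iterations = it,
       converged = converged)
}

#' @keywords internal
.shifted_dens <- function(x, mu, sdv) {
  K <- length(mu)
  ld <- matrix(0, length(x), K)
  for (k in seq_len(K)) ld[, k] <- dnorm(x, mu[k], sdv[k], log = TRUE)
  m <- ld[, 1]
  if (K > 1) for (k in 2:K) m <- pmax(m, ld[, k])
  list(dens = exp(ld - m), shift = sum(m), logdens = ld)
}

#' Log-likelihood of a transformed observation sequence under an HMM
#'
#' Scaled forward recursion; the exact log of the total observation
#' probability summed over all hidden state paths.
#'
#' @param model An `hmm_model` (or any list with `initial`, `transition`,
#'   `means`, `sds`).
#' @param sequence Numeric vector of observations on the transformed
#'   (log1p) scale.
#' @return The log-likelihood, a single number.
#' @export
forward_loglik <- function(model, sequence) {
  if (length(sequence) == 0) stop("empty observation sequence")
  if (any(!is.finite(sequence))) stop("sequence must be finite")
  sd_ <- .shifted_dens(sequence, model$means, model$sds)
  hmm_forward_cpp(sd_$dens, model$transition, model$initial) + sd_$shift
}

#' Viterbi state decoding of a binned track
#'
#' Maximum-probability hidden state path per chromosome. Ties are broken
#' deterministically toward the lower state index.
#'
#' @param model A fitted `hmm_model`.
#' @param track A [binned_track()] at the bin size the model was fitted at.
#' @return An object of class `state_path`: a named list of integer vectors
#'   (states 1..n_states) per chromosome.
#' @export
decode_states <- function(model, track) {
  stopifnot(inherits(track, "binned_track"))
  if (!is.null(model$bin_size) && model$bin_size != track$bin_size)
    stop("track bin size does not match the bin size the model was fitted at")
  logA <- log(model$transition)
  logpi <- log(model$initial)
  path <- lapply(track$values, function(v) {
    x <- log1p(v)
    ld <- .shifted_dens(x, model$means, model$sds)$logdens
    as.integer(hmm_viterbi_cpp(ld, logA, logpi)) + 1L
  })
  structure(path, class = "state_path", layout = track$layout,
            bin_size = track$bin_size)
}

#' Label HMM states by ascending emission mean
#'
#' States sorted by emission mean become, in order: `background`, `class1`
#' (low signal), `class2` (high signal), and `blacklist` (very high
#' artifact signal). Tied means are broken by smaller emission sd, then by
#' state index, with a warning.
#'
#' @param model A fitted 4-state `hmm_model`.
#' @return A character vector of length 4 mapping state index to class.
#' @export
label_states <- function(model) {
  if (model$n_states != 4)
    stop("state labelling is defined for 4-state models")
  if (anyDuplicated(model$means))
    warning("tied emission means; breaking ties by sd then state index")
  ord <- order(model$means, model$sds, seq_along(model$means))
  labels <- character(4)
  labels[ord] <- c("background", "class1", "class2", "blacklist")
  labels
}

#' Convert a decoded state path into classified domains
#'
#' Maximal runs of class 1 and class 2 bins become intervals; background
#' and blacklist bins are excluded (a blacklist run therefore splits a
#' domain). Runs shorter than `min_domain_bins` are dropped; same-class
#' runs separated by at most `max_gap_bins` non-domain bins are merged when
#' `max_gap_bins > 0`.
#'
#' @param path A [decode_states()] result.
#' @param labeling A [label_states()] result.
#' @param bin_size Bin width in bp (defaults to the path's own).
#' @param min_domain_bins Minimum run length kept, default 1 (no filter).
#' @param max_gap_bins Maximum non-domain gap bridged, default 0.
#' @return A domain set `GRanges` (intervals clipped at chromosome ends).
#' @export
segment_domains <- function(path, labeling, bin_size = attr(path, "bin_size"),
                            min_domain_bins = 1L, max_gap_bins = 0L) {
  stopifnot(inherits(path, "state_path"))
  layout <- attr(path, "layout")
  out <- list()
  for (ch in names(path)) {
    cls <- labeling[path[[ch]]]
    r <- rle(cls)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1
    keep <- r$values %in% c("class1", "class2")
    runs <- data.frame(class = r$values[keep],
                       sbin = starts_bin[keep], ebin = ends_bin[keep],
                       stringsAsFactors = FALSE)
    if (nrow(runs) == 0) next
    if (max_gap_bins > 0 && nrow(runs) > 1) {
      # merge consecutive same-class runs when the intervening bins are all
      # non-domain and no wider than the allowed gap
      i <- 1
      merged <- runs[1, , drop = FALSE]
      for (j in 2:nrow(runs)) {
        gap <- runs$sbin[j] - merged$ebin[i] - 1
        gap_classes <- if (gap > 0)
          cls[(merged$ebin[i] + 1):(runs$sbin[j] - 1)] else character(0)
        if (runs$class[j] == merged$class[i] && gap <= max_gap_bins &&
            !any(gap_classes %in% c("class1", "class2"))) {
          merged$ebin[i] <- runs$ebin[j]
        } else {
          merged <- rbind(merged, runs[j, ])
          i <- i + 1
        }
      }
      runs <- merged
    }
    runs <- runs[runs$ebin - runs$sbin + 1 >= min_domain_bins, , drop = FALSE]
    if (nrow(runs) == 0) next
    chlen <- layout$length[[ch]]
    out[[ch]] <- GenomicRanges::GRanges(
      ch,
      IRanges::IRanges(start = (runs$sbin - 1) * bin_size + 1,
                       end = pmin(runs$ebin * bin_size, chlen)),
      class = runs$class)
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges(class = character(0))
  } else {
    gr <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  }
  GenomeInfoDb::seqlevels(gr) <- layout$chrom
  GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  as_domain_set(gr)
}

#' Simulate observation sequences from an HMM
#'
#' Draws hidden state paths from the Markov chain and Gaussian emissions
#' per state; useful for parameter-recovery checks.
#'
#' @param model List with `initial`, `transition`, `means`, `sds`.
#' @param lengths Integer vector of sequence lengths.
#' @param seed Integer seed.
#' @return List with elements `states` and `values` (lists of vectors).
#' @export
simulate_hmm <- function(model, lengths, seed = 1L) {
  set.seed(as.integer(seed))
  K <- length(model$means)
  res_s <- list()
  res_v <- list()
  for (i in seq_along(lengths)) {
    n <- lengths[i]
    s <- integer(n)
    s[1] <- sample.int(K, 1, prob = model$initial)
    for (t in seq_len(n)[-1])
      s[t] <- sample.int(K, 1, prob = model$transition[s[t - 1], ])
    res_s[[i]] <- s
    res_v[[i]] <- rnorm(n, model$means[s], model$sds[s])
  }
  list(states = res_s, values = res_v)
}

#' Serialize a fitted HMM to JSON
#' @param model An `hmm_model`.
#' @param path Output file.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(n_states = model$n_states, initial = model$initial,
         transition = model$transition, means = model$means, sds = model$sds,
         loglik = model$loglik, iterations = model$iterations,
         converged = model$converged, bin_size = model$bin_size,
         transform = model$transform),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
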