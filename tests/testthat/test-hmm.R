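test_that("forward log-likelihood matches exhaustive path enumeration", {
  for (seed in 1:12) {
    set.seed(100 + seed)
    K <- sample(1:4, 1)
    Tn <- sample(1:8, 1)
    m <- random_model(K, seed)
    x <- rnorm(Tn, sample(m$means, Tn, replace = TRUE), 1)
    expect_equal(forward_loglik(m, x), enum_loglik(m, x), tolerance = 1e-12)
  }
})

test_that("length-1 forward likelihood is the initial-weighted density", {
  m <- random_model(3, 7)
  x <- 0.4
  expect_equal(forward_loglik(m, x),
               log(sum(m$initial * dnorm(x, m$means, m$sds))))
  expect_error(forward_loglik(m, numeric(0)), "empty")
})

test_that("duplicating a state with split initial mass keeps the likelihood", {
  m <- random_model(2, 3)
  A <- m$transition
  dup <- list(
    initial = c(m$initial[1] / 2, m$initial[1] / 2, m$initial[2]),
    transition = rbind(c(A[1, 1] / 2, A[1, 1] / 2, A[1, 2]),
                       c(A[1, 1] / 2, A[1, 1] / 2, A[1, 2]),
                       c(A[2, 1] / 2, A[2, 1] / 2, A[2, 2])),
    means = c(m$means[1], m$means[1], m$means[2]),
    sds = c(m$sds[1], m$sds[1], m$sds[2]))
  set.seed(8)
  x <- rnorm(6)
  expect_equal(forward_loglik(dup, x), forward_loglik(m, x),
               tolerance = 1e-12)
})

test_that("Viterbi decoding equals exhaustive argmax on short sequences", {
  for (seed in 1:10) {
    set.seed(200 + seed)
    K <- sample(2:4, 1)
    Tn <- sample(2:6, 1)
    m <- random_model(K, 50 + seed)
    m$bin_size <- 1000
    x <- rnorm(Tn, sample(m$means, Tn, replace = TRUE), 1)
    tr <- make_track(pmax(expm1(x), 0), bin_size = 1000)
    path <- decode_states(structure(m, class = "hmm_model"), tr)
    expect_equal(path$chr1,
                 unname(enum_viterbi(m, log1p(pmax(expm1(x), 0)))))
  }
})

test_that("single-bin decoding is the argmax of initial times density", {
  m <- random_model(4, 9)
  m$bin_size <- 1000
  v <- 2.5
  tr <- make_track(v, bin_size = 1000)
  path <- decode_states(structure(m, class = "hmm_model"), tr)
  expect_equal(path$chr1,
               which.max(log(m$initial) + dnorm(log1p(v), m$means, m$sds,
                                                log = TRUE)))
})

test_that("a single-state fit recovers the sample mean and population sd", {
  set.seed(11)
  v <- rlnorm(500)
  tr <- make_track(v, bin_size = 1000)
  m <- fit_hmm(tr, n_states = 1, n_restarts = 1, max_iter = 20)
  x <- log1p(v)
  expect_equal(m$means, mean(x), tolerance = 1e-8)
  expect_equal(m$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
})

test_that("constant-valued input is rejected as degenerate", {
  tr <- make_track(rep(2, 100))
  expect_error(fit_hmm(tr), "degenerate")
})

test_that("Baum-Welch log-likelihood trace never decreases", {
  set.seed(21)
  model <- list(initial = c(0.5, 0.5),
                transition = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                means = c(1, 3), sds = c(0.5, 0.5))
  sim <- simulate_hmm(model, lengths = c(800, 700), seed = 5)
  vals <- lapply(sim$values, function(y) pmax(expm1(y), 0))
  names(vals) <- c("chr1", "chr2")
  tr <- make_track(vals, bin_size = 1000)
  m <- fit_hmm(tr, n_states = 2, n_restarts = 2, max_iter = 50)
  expect_true(all(diff(m$loglik_trace) > -1e-6 * (1 + abs(m$loglik_trace[-1]))))
})

test_that("emission means of a planted sticky 4-state model are recovered", {
  truth <- list(initial = rep(0.25, 4),
                transition = matrix(0.01 / 3, 4, 4),
                means = c(2, 3, 5, 10), sds = rep(0.5, 4))
  diag(truth$transition) <- 0.99
  sim <- simulate_hmm(truth, lengths = rep(10000, 5), seed = 31)
  vals <- lapply(sim$values, function(y) pmax(expm1(y), 0))
  names(vals) <- paste0("chr", 1:5)
  tr <- make_track(vals, bin_size = 10000)
  m <- fit_hmm(tr, n_states = 4, seed = 2, n_restarts = 3)
  expect_lt(max(abs(sort(m$means) - truth$means)), 0.15)
  # decoded classes agree with the planted path at >= 95% of bins
  path <- decode_states(m, tr)
  ord <- order(m$means)
  relabel <- integer(4)
  relabel[ord] <- 1:4
  agree <- mean(unlist(Map(function(p, s) relabel[p] == s,
                           path, sim$states)))
  expect_gt(agree, 0.95)
})

test_that("states are labelled by ascending emission mean", {
  m <- list(n_states = 4, means = c(8, 0, 3, 1), sds = rep(0.5, 4))
  expect_equal(label_states(m),
               c("blacklist", "background", "class2", "class1"))
  m2 <- list(n_states = 4, means = c(0, 1, 3, 8), sds = rep(0.5, 4))
  expect_equal(label_states(m2),
               c("background", "class1", "class2", "blacklist"))
  m3 <- list(n_states = 4, means = c(0, 1, 1, 8), sds = c(0.5, 0.7, 0.3, 0.5))
  expect_warning(lab <- label_states(m3), "tie")
  expect_equal(lab, c("background", "class2", "class1", "blacklist"))
})

test_that("segment_domains turns labelled runs into intervals", {
  layout <- make_layout(60000)
  lab <- c("background", "class1", "class2", "blacklist")
  path <- structure(list(chr1 = c(1L, 2L, 2L, 3L, 3L, 1L)),
                    class = "state_path", layout = layout, bin_size = 10000)
  d <- segment_domains(path, lab)
  expect_equal(GenomicRanges::start(d), c(10001, 30001))
  expect_equal(GenomicRanges::end(d), c(30000, 50000))
  expect_equal(d$class, c("class1", "class2"))

  none <- structure(list(chr1 = rep(1L, 6)), class = "state_path",
                    layout = layout, bin_size = 10000)
  expect_length(segment_domains(none, lab), 0)

  # a blacklist run splits a domain when no gap bridging is allowed
  split <- structure(list(chr1 = c(2L, 2L, 4L, 2L, 2L, 1L)),
                     class = "state_path", layout = layout, bin_size = 10000)
  d2 <- segment_domains(split, lab)
  expect_length(d2, 2)
  expect_equal(d2$class, c("class1", "class1"))
  # and is bridged when max_gap_bins allows
  d3 <- segment_domains(split, lab, max_gap_bins = 1)
  expect_length(d3, 1)
  expect_equal(GenomicRanges::width(d3), 50000)
  # min_domain_bins drops short runs
  d4 <- segment_domains(split, lab, min_domain_bins = 3)
  expect_length(d4, 0)
})

test_that("domain bp equals domain-class bins times bin size", {
  set.seed(33)
  layout <- make_layout(500000)
  states <- sample(1:4, 50, replace = TRUE)
  lab <- c("background", "class1", "class2", "blacklist")
  path <- structure(list(chr1 = states), class = "state_path",
                    layout = layout, bin_size = 10000)
  d <- segment_domains(path, lab)
  expect_equal(sum(GenomicRanges::width(d)), sum(states %in% 2:3) * 10000)
})
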