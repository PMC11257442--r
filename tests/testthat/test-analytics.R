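test_that("domain statistics count bp and contiguous lengths exactly", {
  layout <- genome_layout("chr1", 1e7) # 1,000 bins of 10 kb
  # 59% of the genome in domains: 300 + 290 bins
  d <- domain_set("chr1", c(1, 4e6 + 1), c(3e6, 6.9e6),
                  c("class1", "class2"), layout)
  st <- domain_stats(d, layout)
  expect_equal(st$coverage_fraction, 0.59)
  expect_equal(st$per_class$bp, c(3e6, 2.9e6))
  expect_equal(st$per_class$n, c(1, 1))
})

test_that("median contiguous length is class-agnostic after coalescing", {
  layout <- genome_layout("chr1", 1e6)
  # class1 then abutting class2 form one 30-kb contiguous tract
  d <- domain_set("chr1", c(1, 10001, 100001, 200001),
                  c(10000, 30000, 120000, 210000),
                  c("class1", "class2", "class1", "class2"), layout)
  st <- domain_stats(d, layout)
  expect_equal(st$median_contiguous_bp, 20000)
})

test_that("empty domain sets report zero coverage and missing median", {
  layout <- genome_layout("chr1", 1e6)
  empty <- domain_set(character(0), numeric(0), numeric(0), character(0),
                      layout)
  st <- domain_stats(empty, layout)
  expect_equal(st$coverage_fraction, 0)
  expect_true(is.na(st$median_contiguous_bp))
})

test_that("domains beyond the chromosome end are rejected", {
  layout <- genome_layout("chr1", 1e4)
  d <- domain_set("chr1", 5001, 20000, "class1")
  expect_error(domain_stats(d, layout), "exceeds")
})

test_that("sharing of identical and disjoint sets hits the limits", {
  layout <- genome_layout("chr1", 1e6)
  d <- domain_set("chr1", c(1, 50001), c(20000, 90000),
                  c("class1", "class2"), layout)
  four <- list(WT = d, LBRKO = d, TKO = d, QKO = d)
  sh <- condition_sharing(four)
  expect_equal(sh$shared_all_fraction, 1.0)
  dis <- list(A = domain_set("chr1", 1, 1000, "class1", layout),
              B = domain_set("chr1", 2001, 3000, "class1", layout))
  expect_equal(condition_sharing(dis)$shared_all_fraction, 0)
})

test_that("bp-mode sharing patterns match per-bp membership counting", {
  layout <- genome_layout("chr1", 200)
  sets <- list(A = domain_set("chr1", c(1, 101), c(50, 160), rep("class1", 2), layout),
               B = domain_set("chr1", 31, 120, "class2", layout),
               C = domain_set("chr1", c(41, 151), c(70, 180), rep("class1", 2), layout))
  sh <- condition_sharing(sets)
  memb_bp <- matrix(FALSE, 200, 3, dimnames = list(NULL, names(sets)))
  for (i in 1:3) {
    d <- sets[[i]]
    for (j in seq_along(d))
      memb_bp[GenomicRanges::start(d)[j]:GenomicRanges::end(d)[j], i] <- TRUE
  }
  in_union <- rowSums(memb_bp) > 0
  expect_equal(sh$union_bp, sum(in_union))
  pat_bp <- apply(memb_bp[in_union, ], 1, function(z)
    paste(names(sets)[z], collapse = "&"))
  oracle <- table(pat_bp)
  got <- setNames(sh$patterns$bp, sh$patterns$pattern)
  expect_equal(got[names(oracle)], setNames(as.numeric(oracle), names(oracle)))
  # conservation: pattern bp sums to union bp
  expect_equal(sum(sh$patterns$bp), sh$union_bp)
  expect_equal(sh$shared_all_fraction,
               sum(rowSums(memb_bp) == 3) / sum(in_union))
})

test_that("domain-mode sharing respects the reciprocal-overlap rule", {
  layout <- genome_layout("chr1", 1e4)
  a <- domain_set("chr1", 1, 1000, "class1", layout)
  # 60% reciprocal overlap with the union region
  b <- domain_set("chr1", 401, 1000, "class1", layout)
  sh <- condition_sharing(list(A = a, B = b), mode = "domain",
                          min_reciprocal = 0.5)
  expect_equal(sh$shared_all_fraction, 1)
  sh2 <- condition_sharing(list(A = a, B = b), mode = "domain",
                           min_reciprocal = 0.7)
  expect_equal(sh2$shared_all_fraction, 0)
})

test_that("meta-domain profiles rescale bodies and average domains", {
  # constant track -> flat profile
  tr <- make_track(rep(3, 100), bin_size = 1000)
  d <- domain_set("chr1", c(20001, 60001), c(30000, 75000),
                  c("class1", "class2"), tr$layout)
  prof <- meta_domain_profile(tr, d, body_bins = 20, flank_bp = 5000)
  expect_equal(length(prof), 30)
  expect_true(all(abs(prof - 3) < 1e-12))

  # one domain with a linear ramp -> linearly interpolated resample
  v <- rep(0, 100)
  v[21:30] <- 1:10
  tr2 <- make_track(v, bin_size = 1000)
  d1 <- domain_set("chr1", 20001, 30000, "class1", tr2$layout)
  prof2 <- meta_domain_profile(tr2, d1, body_bins = 19, flank_bp = 0)
  expect_equal(as.numeric(prof2), approx(1:10, 1:10, n = 19)$y)

  # two identical domains average to the single-domain profile
  v3 <- rep(0, 100)
  v3[21:30] <- 1:10
  v3[61:70] <- 1:10
  tr3 <- make_track(v3, bin_size = 1000)
  d2 <- domain_set("chr1", c(20001, 60001), c(30000, 70000),
                   rep("class1", 2), tr3$layout)
  expect_equal(meta_domain_profile(tr3, d2, body_bins = 19, flank_bp = 0),
               prof2)
  expect_error(meta_domain_profile(tr, d[0], body_bins = 10), "empty")
})

test_that("profiles are linear in track scaling", {
  set.seed(5)
  tr <- make_track(runif(200), bin_size = 1000)
  d <- domain_set("chr1", c(10001, 120001), c(40000, 150000),
                  c("class1", "class2"), tr$layout)
  p1 <- meta_domain_profile(tr, d, body_bins = 25, flank_bp = 5000)
  tr2 <- normalize_track(tr, compute_scale_factor(10000))
  p2 <- meta_domain_profile(tr2, d, body_bins = 25, flank_bp = 5000)
  expect_equal(p2, 3 * p1)
})

test_that("signal dispersion uses midpoint membership and population sd", {
  tr <- make_track(c(1, 2, 3, 4, 100, 100), bin_size = 1000)
  # first four bins selected by midpoint containment
  reg <- domain_set("chr1", 1, 4000, "class1", tr$layout)
  disp <- signal_dispersion(tr, reg)
  expect_equal(disp$mean, 2.5)
  expect_equal(disp$sd, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(disp$n_bins, 4L)
  # constant track has zero dispersion
  const <- make_track(rep(7, 10))
  expect_equal(signal_dispersion(const)$sd, 0)
  # whole genome equals a full-layout region set
  full <- domain_set("chr1", 1, 6000, "class1", tr$layout)
  expect_equal(signal_dispersion(tr, full), signal_dispersion(tr, NULL))
})
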