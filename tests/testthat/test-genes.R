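layout_g <- genome_layout("chr1", 1e6)

gene_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = "chr1", start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), stringsAsFactors = FALSE)))
}

test_that("genes are assigned by majority gene-body bp with stated ties", {
  doms <- domain_set("chr1", c(1, 50001), c(20000, 70000),
                     c("class2", "class1"), layout_g)
  genes <- gene_df(list("inside2", 5001, 15000),    # fully inside class2
                   list("outside", 200001, 210000), # no overlap
                   list("mostly1", 50001, 66666),   # ~60% class1 in-body? no: fully in
                   list("part1", 62001, 82000),     # 8 kb class1 / 12 kb outside
                   list("maj1", 58001, 78000),      # 12 kb class1 / 8 kb outside
                   list("tie_dom", 60001, 80000))   # 10 kb class1 / 10 kb outside
  a <- assign_genes(genes, doms)
  got <- setNames(as.character(a$category), a$gene_id)
  expect_equal(got[["inside2"]], "class2")
  expect_equal(got[["outside"]], "outside")
  expect_equal(got[["part1"]], "outside")
  expect_equal(got[["maj1"]], "class1")
  expect_equal(got[["tie_dom"]], "class1") # domain/outside tie -> domain

  # class1/class2 bp tie goes to class2
  doms2 <- domain_set("chr1", c(1, 10001), c(10000, 20000),
                      c("class1", "class2"), layout_g)
  tie <- gene_df(list("tiecc", 5001, 15000))
  a2 <- assign_genes(tie, doms2)
  expect_equal(as.character(a2$category), "class2")

  expect_error(assign_genes(gene_df(list("far", 2e6, 2e6 + 100)), doms,
                            layout = layout_g), "outside the genome")
})

test_that("TPM normalizes to one million per sample", {
  genes <- gene_df(list("g1", 1, 1000), list("g2", 2001, 6000))
  genes$effective_length <- c(1000, 2000)
  mat <- matrix(c(10, 10, 40, 40), 2, 2, byrow = FALSE,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- counts_matrix(mat, c("wt", "wt"))
  tp <- tpm(cm, genes)
  expect_equal(unname(colSums(tp)), c(1e6, 1e6))
  # equal counts, lengths L and 2L -> TPM ratio 2:1
  cm2 <- counts_matrix(matrix(c(5, 5), 2, 1,
                              dimnames = list(c("g1", "g2"), "s1")),
                       "wt")
  tp2 <- tpm(cm2, genes)
  expect_equal(tp2["g1", 1] / tp2["g2", 1], 2)
  # a single gene takes the whole million
  single <- counts_matrix(matrix(7, 1, 1, dimnames = list("g1", "s1")), "wt")
  expect_equal(unname(tpm(single, genes[1, ])[1, 1]), 1e6)
  zero <- counts_matrix(matrix(0, 1, 1, dimnames = list("g1", "s1")), "wt")
  expect_error(tpm(zero, genes[1, ]), "zero total rate")
})

test_that("expressed fractions follow the mean-TPM threshold per category", {
  genes <- gene_df(list("g1", 1, 1000), list("g2", 2001, 3000),
                   list("g3", 4001, 5000))
  assignment <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    category = factor(c("outside", "class1", "class1"),
                      levels = c("outside", "class1", "class2")))
  tpm_mat <- matrix(c(10, 10, 10, 10, 2, 4), 3, 2, byrow = TRUE,
                    dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  cm <- counts_matrix(matrix(1L, 3, 2, dimnames = dimnames(tpm_mat)),
                      c("wt", "wt"))
  fr <- expressed_fraction(assignment, tpm_mat, cm, "wt", threshold = 5)
  expect_equal(unname(fr), c(1, 0.5, NA))
  fr2 <- expressed_fraction(assignment, tpm_mat, cm, "wt", threshold = Inf)
  expect_equal(unname(fr2[1:2]), c(0, 0))
})

test_that("gene flow cross-tabulation conserves the gene universe", {
  mk <- function(cats) data.frame(
    gene_id = paste0("g", seq_along(cats)),
    category = factor(cats, levels = c("outside", "class1", "class2")))
  a <- mk(c("outside", "class1", "class2", "outside", "class1", "outside"))
  b <- mk(c("class1", "class1", "outside", "outside", "class2", "class2"))
  fl <- domain_flow(a, b)
  # hand cross-tabulation: in/in = genes 2,5; out->in = 1,6; in->out = 3; never = 4
  expect_equal(unname(fl$counts),
               c(constitutive = 2, gained = 2, lost = 1, never = 1),
               ignore_attr = TRUE)
  expect_equal(sum(fl$counts), 6)
  identical_flow <- domain_flow(a, a)
  expect_equal(unname(identical_flow$counts[c("gained", "lost")]), c(0, 0))
  expect_error(domain_flow(a, mk(c("outside"))), "universe")

  # conservation on random instances
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1)
    a <- mk(sample(c("outside", "class1", "class2"), n, replace = TRUE))
    b <- mk(sample(c("outside", "class1", "class2"), n, replace = TRUE))
    fl <- domain_flow(a, b)
    expect_equal(sum(fl$counts), n)
    expect_equal(sum(fl$crosstab), n)
  }
})

test_that("median-of-ratios size factors behave like library sizes", {
  set.seed(9)
  mat <- matrix(rnbinom(3000, mu = 50, size = 5) + 1L, 1000, 3,
                dimnames = list(paste0("f", 1:1000), paste0("s", 1:3)))
  m2 <- cbind(mat[, 1], mat[, 1], mat[, 1])
  dimnames(m2) <- list(rownames(mat), paste0("s", 1:3))
  same <- counts_matrix(m2, c("a", "a", "a"))
  expect_equal(unname(size_factors(same)), c(1, 1, 1))

  doubled <- mat
  doubled[, 2] <- mat[, 1] * 2L
  doubled[, 3] <- mat[, 1]
  doubled[, 1] <- mat[, 1]
  cm <- counts_matrix(doubled, c("a", "a", "a"))
  sf <- size_factors(cm)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # invariant to feature order
  perm <- counts_matrix(doubled[sample(nrow(doubled)), ], c("a", "a", "a"))
  expect_equal(sort(unname(size_factors(perm))), sort(unname(sf)))
})

test_that("size factors agree with the established median-of-ratios engine", {
  skip_if_not_installed("DESeq2")
  set.seed(10)
  mat <- matrix(rnbinom(4000, mu = 80, size = 8), 1000, 4,
                dimnames = list(paste0("f", 1:1000), paste0("s", 1:4)))
  depths <- c(1, 2, 0.6, 1.4)
  for (j in 1:4) mat[, j] <- rpois(nrow(mat), mat[, j] * depths[j])
  cm <- counts_matrix(mat, rep("a", 4))
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-8)
})

test_that("Kruskal-Wallis H matches the direct rank formula", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- compare_groups(groups)
  # no ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  H_oracle <- 12 / (9 * 10) * 3 * (2^2 + 5^2 + 8^2) - 3 * 10
  expect_equal(res$H, H_oracle)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))
})

test_that("two-group Kruskal-Wallis equals the asymptotic rank-sum test", {
  set.seed(12)
  a <- round(rnorm(12, 0, 2), 1) # rounding induces ties
  b <- round(rnorm(15, 1, 2), 1)
  res <- compare_groups(list(a = a, b = b))
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$p, w$p.value, tolerance = 1e-10)
})

test_that("completely tied data give H = 0 and p = 1", {
  res <- compare_groups(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
})

test_that("Dunn z statistics follow the pooled-rank-variance formula", {
  res <- compare_groups(list(a = c(1, 2), b = c(3, 4)))
  # N = 4, no ties: var = 4*5/12; rank means 1.5 vs 3.5
  z_oracle <- (1.5 - 3.5) / sqrt(4 * 5 / 12 * (1 / 2 + 1 / 2))
  expect_equal(res$pairwise$z, z_oracle)
  expect_equal(res$pairwise$p, 2 * pnorm(-abs(z_oracle)))
})
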