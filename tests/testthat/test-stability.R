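test_that("the F-statistic matches hand-computed one-way ANOVA", {
  labs <- rep(c("TFN", "TFP"), each = 3)
  expect_equal(f_statistic(c(1, 2, 3, 1, 2, 3), labs), 0)

  labs2 <- rep(c("TFN", "TFP"), each = 2)
  # SSB = 4 (df 1), SSW = 1 (df 2) -> F = 4 / 0.5 = 8
  expect_equal(f_statistic(c(1, 2, 3, 4), labs2), 8)

  # zero within-group variance with separated means -> large sentinel
  expect_gt(f_statistic(c(0, 0, 1, 1), labs2), 1e11)
  # zero within-group variance, equal means -> 0
  expect_equal(f_statistic(c(1, 1, 1, 1), labs2), 0)

  # random cases against an independently coded ANOVA decomposition
  set.seed(42)
  for (i in 1:20) {
    v <- stats::rnorm(12)
    g <- rep(c("TFN", "TFP"), c(5, 7))
    m1 <- mean(v[g == "TFN"]); m2 <- mean(v[g == "TFP"])
    gm <- mean(v)
    ssb <- 5 * (m1 - gm)^2 + 7 * (m2 - gm)^2
    ssw <- sum((v[g == "TFN"] - m1)^2) + sum((v[g == "TFP"] - m2)^2)
    expect_equal(f_statistic(v, g), (ssb / 1) / (ssw / 10))
  }
})

test_that("entropy follows the equal-width binning definition", {
  expect_equal(shannon_entropy(rep(3.7, 10)), 0)
  # four values filling 4 bins equally -> 2 bits
  expect_equal(shannon_entropy(c(0.5, 1.5, 2.5, 3.5), bins = 4), 2)
  expect_equal(shannon_entropy(c(0, 0, 0, 10), bins = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("CV uses the population SD and is scale-invariant", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)
  v <- c(1, 4, 9, 16)
  expect_equal(coefficient_of_variation(v * 7),
               coefficient_of_variation(v))
  expect_equal(coefficient_of_variation(rep(0, 5)), 0)
})

test_that("outlier sum flags by the 1xIQR fences and sums |x - median|", {
  expect_equal(outlier_sum(c(1, 2, 3, 4)), 0)
  # type-7 quartiles of (1,2,3,4,100): Q1 = 2, Q3 = 4, fences [0, 6]
  expect_equal(outlier_sum(c(1, 2, 3, 4, 100)), 97)
  expect_equal(outlier_sum(rep(5, 6)), 0)
  expect_error(outlier_sum(c(1, 2, 3)), "at least 4")
  # conventional 1.5 coefficient is available
  expect_equal(outlier_sum(c(1, 2, 3, 4, 6.9), coef = 1.5), 0)
})

test_that("MAD is the raw median absolute deviation", {
  expect_equal(median_absolute_deviation(c(1, 2, 3, 4, 100)), 1)
  expect_equal(median_absolute_deviation(rep(2, 4)), 0)
  v <- c(3, 9, 1, 4)
  expect_equal(median_absolute_deviation(v + 17),
               median_absolute_deviation(v))
})

test_that("all five metrics ignore sample order; F ignores label swap", {
  set.seed(7)
  v <- stats::rexp(20) * 10
  labs <- rep(c("TFN", "TFP"), each = 10)
  perm <- sample(20)
  expect_equal(f_statistic(v[perm], labs[perm]), f_statistic(v, labs))
  expect_equal(shannon_entropy(v[perm]), shannon_entropy(v))
  expect_equal(coefficient_of_variation(v[perm]), coefficient_of_variation(v))
  expect_equal(outlier_sum(v[perm]), outlier_sum(v))
  expect_equal(median_absolute_deviation(v[perm]), median_absolute_deviation(v))
  swapped <- ifelse(labs == "TFN", "TFP", "TFN")
  expect_equal(f_statistic(v, swapped), f_statistic(v, labs))
})

test_that("rank fusion averages metric ranks and selects exact quartiles", {
  # 8 genes with hand-assigned metrics: fused score = mean of ranks
  sc <- data.frame(gene_id = paste0("g", 1:8),
                   f_stat = c(1, 2, 3, 4, 5, 6, 7, 8),
                   entropy = c(8, 7, 6, 5, 4, 3, 2, 1),
                   cv = 1:8 / 10,
                   outlier_sum = c(0, 0, 0, 0, 1, 2, 3, 4),
                   mad = c(2, 1, 4, 3, 6, 5, 8, 7))
  fused <- fuse_and_select(sc, quartile = 0.25, anchor = "ERG")
  rank_tab <- cbind(1:8, 8:1, 1:8, c(2.5, 2.5, 2.5, 2.5, 5, 6, 7, 8),
                    c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(fused$fused_score[match(paste0("g", 1:8), fused$gene_id)],
               rowMeans(rank_tab))
  expect_equal(sum(fused$category == "stable"), 2L)
  expect_equal(sum(fused$category == "unstable"), 2L)
  # fused-score tie at the top (g1, g2 both 2.9) broken by gene id
  expect_equal(fused$gene_id[1:2], c("g1", "g2"))
  expect_equal(fused$category[1], "stable")

  # a gene ranked 1 on every metric has fused score 1 and is stable
  sc2 <- data.frame(gene_id = paste0("h", 1:8),
                    f_stat = 1:8, entropy = 1:8, cv = 1:8,
                    outlier_sum = 1:8, mad = 1:8)
  fused2 <- fuse_and_select(sc2, quartile = 0.25)
  expect_equal(fused2$fused_score[fused2$gene_id == "h1"], 1)
  expect_equal(fused2$category[fused2$gene_id == "h1"], "stable")
})

test_that("quartile arithmetic is exact and excludes the anchor", {
  set.seed(3)
  n <- 101 # 100 after dropping ERG
  sc <- data.frame(gene_id = c("ERG", paste0("g", 1:(n - 1))),
                   f_stat = stats::runif(n), entropy = stats::runif(n),
                   cv = stats::runif(n), outlier_sum = stats::runif(n),
                   mad = stats::runif(n))
  fused <- fuse_and_select(sc, quartile = 0.25)
  expect_false("ERG" %in% fused$gene_id)
  expect_equal(sum(fused$category == "stable"), 25L)
  expect_equal(sum(fused$category == "unstable"), 25L)
  expect_equal(length(reference_genes(fused)), 50L)
  expect_equal(sum(fused$category == "stable"),
               floor(0.25 * nrow(fused)))
})

test_that("the per-gene stability table covers all genes and metrics", {
  sim <- simulate_expression(sim_config(n_genes = 40, n_tfn = 10,
                                        n_tfp = 6, seed = 1))
  tab <- gene_stability(sim$expression, sim$labels)
  expect_equal(nrow(tab), 40L)
  expect_true(all(c("f_stat", "entropy", "cv", "outlier_sum", "mad")
                  %in% colnames(tab)))
  expect_true(all(vapply(tab[-1], function(col)
    all(is.finite(col)) && all(col >= 0), logical(1))))
})
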