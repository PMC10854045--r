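test_that("within-sample ranking follows the ascending, tie-averaged rule", {
  m <- matrix(c(5, 1, 3,
                2, 2, 7), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  r <- rank_within_samples(m)
  expect_equal(unname(r[, "s1"]), c(3, 1, 2))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))

  m2 <- tiny_matrix(n_genes = 15, n_samples = 5, seed = 4)
  expect_identical(rank_within_samples(distort_monotone(m2, seed = 1)),
                   rank_within_samples(m2))
})

test_that("reverse degree evaluates the printed formula exactly as written", {
  labs <- stats::setNames(c("TFN", "TFN", "TFP", "TFP"), paste0("s", 1:4))
  # TFN diffs (1-3) twice -> |−4|/2 = 2; TFP diffs (4-2) twice -> 2; R = 2
  ranks <- rbind(ERG = c(1, 1, 4, 4), REF = c(3, 3, 2, 2),
                 f1 = c(2, 2, 1, 1), f2 = c(4, 4, 3, 3))
  colnames(ranks) <- names(labs)
  expect_equal(reverse_degree(ranks, labs, "ERG", "REF"), 2)

  # identical ranks in TFN -> zero factor -> 0
  ranks0 <- rbind(ERG = c(2, 2, 4, 4), REF = c(2, 2, 1, 1))
  colnames(ranks0) <- names(labs)
  expect_equal(reverse_degree(ranks0, labs, "ERG", "REF"), 0)

  # within-group cancellation: TFN diffs +2 and -2 sum to 0 -> 0
  ranksC <- rbind(ERG = c(3, 1, 4, 4), REF = c(1, 3, 2, 2))
  colnames(ranksC) <- names(labs)
  expect_equal(reverse_degree(ranksC, labs, "ERG", "REF"), 0)

  # symmetric under swapping the two genes
  expect_equal(reverse_degree(ranks, labs, "REF", "ERG"),
               reverse_degree(ranks, labs, "ERG", "REF"))
})

test_that("reverse degree matches a literal independent evaluation on random instances", {
  set.seed(99)
  for (i in 1:200) {
    g <- 6L; n <- sample(4:10, 1)
    m <- matrix(stats::rexp(g * n), g, n,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
    labs <- stats::setNames(sample(c("TFN", "TFP"), n, replace = TRUE),
                            colnames(m))
    if (length(unique(labs)) < 2) next
    ranks <- apply(m, 2, rank)
    # literal, loop-based evaluation
    s_tfn <- 0; s_tfp <- 0; mm <- 0; nn <- 0
    for (s in colnames(m)) {
      d <- ranks["g1", s] - ranks["g2", s]
      if (labs[[s]] == "TFN") { s_tfn <- s_tfn + d; mm <- mm + 1 }
      else { s_tfp <- s_tfp + d; nn <- nn + 1 }
    }
    expected <- sqrt(abs(s_tfn) / mm * abs(s_tfp) / nn)
    expect_equal(reverse_degree(rank_within_samples(m), labs, "g1", "g2"),
                 expected)
  }
})

test_that("the unsigned reverse degree rewards distant non-reversing pairs", {
  # a pair far apart in every sample outranks a genuine reversal
  labs <- stats::setNames(rep(c("TFN", "TFP"), each = 3), paste0("s", 1:6))
  x <- rbind(ERG = c(4, 4, 4, 6, 6, 6),    # crosses REV between groups
             REV = c(5, 5, 5, 5, 5, 5),
             LOW = c(1, 1, 1, 1, 1, 1),    # always far below ERG
             HI = c(9, 9, 9, 9, 9, 9),
             F1 = c(2, 2, 2, 2, 2, 2),
             F2 = c(3, 3, 3, 3, 3, 3))
  colnames(x) <- names(labs)
  r <- rank_within_samples(x)
  rd_rev <- reverse_degree(r, labs, "ERG", "REV")
  rd_far <- reverse_degree(r, labs, "ERG", "LOW")
  expect_gt(rd_far, rd_rev)
  # the signed variant zeroes the same-direction pair but keeps the reversal
  expect_equal(reverse_degree(r, labs, "ERG", "LOW", signed = TRUE), 0)
  expect_equal(reverse_degree(r, labs, "ERG", "REV", signed = TRUE), rd_rev)
})

test_that("pair F-1 picks the better orientation and ties vote TFN", {
  labs <- stats::setNames(rep(c("TFN", "TFP"), each = 3), paste0("s", 1:6))
  x <- rbind(ERG = c(1, 1, 1, 5, 5, 5), P = c(3, 3, 3, 3, 3, 3))
  colnames(x) <- names(labs)
  pf <- pair_f1(x, labs, "ERG", "P")
  expect_equal(pf$direction, "gt")
  expect_equal(pf$f1, 1)
  expect_equal(pf$sensitivity, 1)
  expect_equal(pf$specificity, 1)

  # anchor drops in TFP -> the "lt" orientation wins
  x2 <- rbind(ERG = c(5, 5, 5, 1, 1, 1), P = c(3, 3, 3, 3, 3, 3))
  colnames(x2) <- names(labs)
  expect_equal(pair_f1(x2, labs, "ERG", "P")$direction, "lt")

  # an exact tie votes TFN: hurts sensitivity under "gt"
  x3 <- rbind(ERG = c(1, 1, 1, 3, 5, 5), P = c(3, 3, 3, 3, 3, 3))
  colnames(x3) <- names(labs)
  pf3 <- pair_f1(x3, labs, "ERG", "P")
  expect_equal(pf3$sensitivity, 2 / 3)
  expect_equal(pf3$specificity, 1)

  # harmonic-mean zero when sensitivity is zero
  expect_equal(harmonic_f1(0, 0.9), 0)
  expect_equal(harmonic_f1(0, 0), 0)
})

test_that("pair statistics are invariant to per-sample monotone transforms", {
  set.seed(12)
  sim <- simulate_expression(sim_config(n_genes = 30, n_tfn = 8, n_tfp = 6,
                                        seed = 12))
  x <- sim$expression; labs <- sim$labels
  d <- distort_monotone(x, seed = 77)
  p <- sim$planted_partners[1]
  expect_equal(pair_f1(d, labs, "ERG", p), pair_f1(x, labs, "ERG", p))
  expect_equal(reverse_degree(rank_within_samples(d), labs, "ERG", p),
               reverse_degree(rank_within_samples(x), labs, "ERG", p))
})

test_that("candidate pool implements the top-k / top-fraction union rule", {
  # same 10 pairs lead both rankings, no further overlap -> pool of 10
  sc <- data.frame(partner = sprintf("q%02d", 1:50), direction = "gt",
                   reverse_degree = 50:1, sensitivity = 0.9,
                   specificity = 0.9, f1 = seq(0.99, 0.50, length.out = 50))
  pool <- candidate_pool(sc, top_frac = 0.2, top_k = 10)
  expect_equal(nrow(pool), 10L)
  expect_setequal(pool$partner, sprintf("q%02d", 1:10))

  # disjoint top-10 lists and empty top-20% intersection -> 20
  sc2 <- data.frame(partner = sprintf("q%02d", 1:40), direction = "gt",
                    reverse_degree = c(40:21, 1:20),
                    sensitivity = 0.9, specificity = 0.9,
                    f1 = c(seq(0.5, 0.59, length.out = 20),
                           seq(0.90, 0.99, length.out = 20)))
  pool2 <- candidate_pool(sc2, top_frac = 0.2, top_k = 10)
  expect_equal(nrow(pool2), 20L)

  # random instances against independent set arithmetic
  set.seed(5)
  for (i in 1:20) {
    n <- sample(30:100, 1)
    sc3 <- data.frame(partner = sprintf("r%03d", 1:n), direction = "gt",
                      reverse_degree = stats::runif(n), sensitivity = 0.5,
                      specificity = 0.5, f1 = stats::runif(n))
    pool3 <- candidate_pool(sc3, top_frac = 0.2, top_k = 10)
    ord_r <- sc3$partner[order(-sc3$reverse_degree)]
    ord_f <- sc3$partner[order(-sc3$f1)]
    n20 <- ceiling(0.2 * n)
    expected <- union(union(ord_r[1:10], ord_f[1:10]),
                      intersect(ord_r[1:n20], ord_f[1:n20]))
    expect_setequal(pool3$partner, expected)
  }
})

test_that("planted partners top the F-1 ranking and enter the pool", {
  sim <- simulate_expression(sim_config(erg_shift = 3, seed = 21))
  fused <- fuse_and_select(gene_stability(sim$expression, sim$labels))
  refs <- union(reference_genes(fused), sim$planted_partners)
  sc <- screen_pairs(sim$expression, sim$labels, refs)
  expect_true(all(sim$planted_partners %in% sc$partner[1:8]))
  pool <- candidate_pool(sc)
  expect_true(all(sim$planted_partners %in% pool$partner))
})
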