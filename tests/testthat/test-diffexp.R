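test_that("exact-test p-values match closed forms and brute-force summation", {
  # symmetric observation -> capped at 1
  expect_equal(ac_pvalue(7, 7, 1e6, 1e6), 1)
  # geometric series: x = 0, y = 5, equal libraries
  expect_equal(ac_pvalue(0, 5, 1e6, 1e6), 0.0625, tolerance = 1e-12)
  # brute-force summation oracle on unequal libraries
  expect_equal(ac_pvalue(3, 12, 1e6, 2e6), ac_brute(3, 12, 1e6, 2e6),
               tolerance = 1e-10)
  # dual route: negative-binomial tail closed form, 1e-10 relative
  cases <- list(c(0, 5, 1e6, 1e6), c(3, 12, 1e6, 2e6), c(40, 12, 2e6, 1e6),
                c(100, 180, 5e5, 7e5), c(1, 0, 1e4, 3e4))
  for (cs in cases) {
    p_pkg <- ac_pvalue(cs[1], cs[2], cs[3], cs[4])
    p_nb <- ac_nb(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p_pkg, p_nb, tolerance = 1e-10)
  }
})

test_that("the two test orientations agree closely and are exact when x = y", {
  # the conditional formulation fixes one count and sums tails over the
  # other, so the two orientations are distinct (though closely agreeing)
  # tests; only the symmetric observation is exactly exchangeable
  set.seed(11)
  for (i in 1:20) {
    x <- rpois(1, 50); y <- rpois(1, 20)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    p1 <- ac_pvalue(x, y, N1, N2)
    p2 <- ac_pvalue(y, x, N2, N1)
    expect_lt(abs(log10(p1) - log10(p2)), 1)
  }
  expect_equal(ac_pvalue(9, 9, 5e5, 5e5), ac_pvalue(9, 9, 5e5, 5e5))
  expect_equal(ac_pvalue(9, 9, 5e5, 5e5), 1)
  expect_error(ac_pvalue(-1, 2, 10, 10), "non-negative")
})

test_that("BH adjustment follows the step-up rule and preserves order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
})

test_that("DEG calling applies all three filters with inclusive boundaries", {
  # two samples engineered so thresholds sit exactly on the boundary
  counts <- tibble::tibble(
    gene_id = c("hit", "lowexpr", "flat"),
    length = c(1000L, 1000L, 1000L),
    s1 = c(2L, 0L, 100L),
    s2 = c(50L, 1L, 110L))
  degs <- call_degs(counts, threshold_set(2, 0.05, 2),
                    library_sizes = c(1e5, 1e5), pseudocount = 0)
  hit <- degs[degs$gene_id == "hit", ]
  expect_true(hit$passes_filters)
  expect_equal(hit$direction, "up")
  expect_false(degs$passes_filters[degs$gene_id == "flat"])
  # inclusive boundary: q == max_fdr, |lr| == min_abs_log2, rpkm == min_rpkm
  fake <- tibble::tibble(gene_id = "g", length = 1000L, s1 = 4L, s2 = 16L)
  d <- call_degs(fake, threshold_set(2, 1, 2),
                 library_sizes = c(2e6, 2e6), pseudocount = 0)
  expect_equal(abs(d$log2_ratio), 2)
  expect_equal(compute_rpkm(fake, c(2e6, 2e6))$s1, 2)  # sits on min_rpkm
  expect_true(d$passes_filters)
  expect_error(call_degs(counts[0, ], threshold_set()), "at least one gene")
})

test_that("null simulations stay at or below the nominal flag rate", {
  fractions <- vapply(1:100, function(s) {
    sim <- simulate_counts(simulation_config(
      n_genes = 200, library_sizes = rep(5e4, 3), seed = s))
    degs <- call_degs(sim$counts, threshold_set(0, 0.05, 0))
    mean(degs$passes_filters)
  }, numeric(1))
  expect_lte(mean(fractions), 0.05)
})

test_that("planted DE genes at |log2FC| = 3 are recovered at >= 90%", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    de <- list(de_spec(5, c(1, 2), 3), de_spec(15, c(1, 3), 3),
               de_spec(25, c(1, 2), -3), de_spec(35, c(2, 3), 3))
    sim <- simulate_counts(simulation_config(
      n_genes = 150, library_sizes = rep(3e5, 3),
      baseline_log2_sd = 1, de_genes = de, seed = 100 + s))
    degs <- call_degs(sim$counts, threshold_set(2, 0.05, 2))
    found <- dplyr::inner_join(
      sim$truth$de_calls, tibble::as_tibble(degs),
      by = c("gene_id", "comparison"))
    hits <- hits + sum(found$passes_filters &
                         found$direction.x == found$direction.y)
    total <- total + nrow(sim$truth$de_calls)
  }
  expect_gte(hits / total, 0.9)
})

test_that("Venn partition reproduces printed percentages and brute force", {
  # arithmetic reporter on the published-style region counts
  vp <- venn_percentages(c(414, 586, 174, 714, 213, 44), total = 2148)
  expect_equal(vp$count[7], 3)
  expect_equal(vp$percentage, c(19.3, 27.3, 8.1, 33.2, 9.9, 2.0, 0.1))

  # disjoint sets: all intersections empty
  vd <- venn_partition(list(A = c("a", "b"), B = c("c"), C = c("d", "e")))
  expect_equal(vd$count, c(2L, 1L, 2L, 0L, 0L, 0L, 0L))

  # random small sets vs exhaustive enumeration
  set.seed(9)
  for (i in 1:10) {
    universe <- paste0("g", 1:30)
    sets <- list(A = sample(universe, sample(0:20, 1)),
                 B = sample(universe, sample(0:20, 1)),
                 C = sample(universe, sample(0:20, 1)))
    vp <- venn_partition(sets)
    expect_equal(vp$count, venn_brute(sets))
    expect_equal(sum(vp$count), length(unique(unlist(sets))))
  }
})
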