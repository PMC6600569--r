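test_that("identical config and seed give bit-identical simulations", {
  cfg <- simulation_config(n_genes = 80, library_sizes = rep(5e4, 3), seed = 7)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(simulation_config(n_genes = 80,
                                          library_sizes = rep(5e4, 3),
                                          seed = 8))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("module members are more correlated than random non-member pairs", {
  sim <- quick_sim(seed = 3, n_genes = 200,
                   modules = list(module_spec(50, c(0, 2, 2),
                                             within_noise_sd = 0.1)))
  rpkm <- compute_rpkm(sim$counts)
  m <- log2(as.matrix(rpkm[-1]) + 1)
  members <- which(rpkm$gene_id %in% sim$truth$module_membership$gene_id)
  outsiders <- setdiff(seq_len(nrow(m)), members)
  mean_pair_r <- function(idx) {
    cc <- suppressWarnings(cor(t(m[idx, ])))
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  set.seed(1)
  expect_gt(mean_pair_r(members),
            mean_pair_r(sample(outsiders, 50)))
})

test_that("planted DE genes show the requested mean log2 fold change", {
  lfc <- 2
  ratios <- vapply(1:200, function(s) {
    sim <- simulate_counts(simulation_config(
      n_genes = 40, library_sizes = rep(5e4, 3),
      de_genes = list(de_spec(10, c(1, 2), lfc)), seed = s))
    rpkm <- compute_rpkm(sim$counts)
    lr <- log2_ratio(rpkm, c("0h", "2h"), pseudocount = 0)
    lr$log2_ratio[lr$gene_id == "gene_00010"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - lfc), 0.2)
})

test_that("module/DE gene index collisions are rejected with a clear message", {
  expect_error(
    simulation_config(n_genes = 100, library_sizes = rep(1e4, 3),
                      modules = list(module_spec(30, c(0, 1, 2))),
                      de_genes = list(de_spec(20, c(1, 2), 2))),
    "collide")
  expect_error(
    simulation_config(n_genes = 10, library_sizes = rep(1e4, 3),
                      de_genes = list(de_spec(5, c(1, 2), 2),
                                      de_spec(5, c(1, 3), 2))),
    "duplicated")
})

test_that("null simulations respect the three-sample correlation expectation", {
  # For 3 samples under independence the Pearson r density is
  # arcsine-shaped: P(|r| > 0.99) = (2/pi) * acos(0.99) ~ 0.0902.
  expectation <- 2 / pi * acos(0.99)
  sim <- quick_sim(seed = 42, n_genes = 150)
  rpkm <- compute_rpkm(sim$counts)
  cc <- suppressWarnings(
    pearson_matrix(rpkm))
  frac <- mean(abs(cc[upper.tri(cc)]) > 0.99)
  expect_lte(frac, 3 * expectation)
})

test_that("mean counts track library size times latent relative abundance", {
  cfg <- simulation_config(n_genes = 60, library_sizes = rep(2e5, 3),
                           nb_dispersion = 10, n_replicates = 200, seed = 5)
  sim <- simulate_counts(cfg)
  # reconstruct the latent model's expected counts from the documented
  # draw order (lengths, then baselines) under the same seed
  mu <- withr::with_seed(5, {
    len <- as.integer(round(runif(60, 200, 3000)))
    base <- rnorm(60, 5, 2)
    mass <- 2^base * len
    2e5 * mass / sum(mass)
  })
  cm <- as.matrix(sim$counts[grep("^0h_r", names(sim$counts))])
  obs <- rowMeans(cm)
  # replicate-mean within Monte-Carlo error: ~4 sigma of the NB mean
  se <- sqrt((mu + mu^2 / 10) / 200)
  expect_true(all(abs(obs - mu) < 4 * se + 1e-6))
  # column totals match the library size closely
  expect_lt(abs(mean(colSums(cm)) - 2e5) / 2e5, 0.02)
})

test_that("annotation simulation honours degenerate and planted rates", {
  sim <- quick_sim(seed = 2, n_genes = 100,
                   modules = list(module_spec(20, c(0, 1, 2))))
  ann <- simulate_annotation(sim$truth, n_terms = 5, background_rate = 0,
                             enriched_rate = 1, seed = 1)
  planted <- ann$enriched_terms$term[1]
  carriers <- ann$annotation$gene_id[ann$annotation$term == planted]
  members <- sim$truth$module_membership$gene_id
  expect_setequal(carriers, members)
  # determinism
  ann2 <- simulate_annotation(sim$truth, n_terms = 5, background_rate = 0,
                              enriched_rate = 1, seed = 1)
  expect_identical(ann$annotation, ann2$annotation)
  expect_error(simulate_annotation(sim$truth, 5, 0.5, 0.2, 1), "enriched_rate")
})

test_that("planted annotation enrichment is detectable by the exact tail", {
  # module of 50 within a 1000-gene background; enriched 0.8 vs 0.1
  truth <- list(gene_ids = sprintf("g%04d", 1:1000),
                module_membership = tibble::tibble(
                  gene_id = sprintf("g%04d", 1:50), module = 1L))
  hits <- vapply(1:100, function(s) {
    ann <- simulate_annotation(truth, n_terms = 3, background_rate = 0.1,
                               enriched_rate = 0.8, seed = s)
    a <- ann$annotation
    planted <- ann$enriched_terms$term[1]
    k <- sum(a$term == planted & a$gene_id %in% truth$module_membership$gene_id)
    K <- sum(a$term == planted)
    p <- stats::phyper(k - 1, K, 1000 - K, 50, lower.tail = FALSE)
    p < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
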