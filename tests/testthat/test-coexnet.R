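make_expr <- function(m, ids = sprintf("g%02d", seq_len(nrow(m)))) {
  dplyr::bind_cols(tibble::tibble(gene_id = ids),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("pearson matrix matches the textbook formula and flags degeneracies", {
  set.seed(3)
  m <- matrix(rnorm(5 * 6), nrow = 5)
  expr <- make_expr(m)
  cc <- pearson_matrix(expr, log_transform = FALSE)
  # textbook covariance-formula oracle
  for (i in 1:5) for (j in 1:5) {
    num <- mean(m[i, ] * m[j, ]) - mean(m[i, ]) * mean(m[j, ])
    den <- sqrt((mean(m[i, ]^2) - mean(m[i, ])^2) *
                  (mean(m[j, ]^2) - mean(m[j, ])^2))
    expect_equal(cc[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(diag(cc), setNames(rep(1, 5), rownames(cc)))
  # perfect linearity
  lin <- make_expr(rbind(c(1, 2, 3), c(2, 4, 6), c(5, 1, 3)))
  ccl <- suppressWarnings(pearson_matrix(lin, log_transform = FALSE))
  expect_equal(ccl[1, 2], 1)
  # zero-variance genes: correlation zeroed with a warning
  zv <- make_expr(rbind(c(1, 1, 1, 1), c(1, 2, 3, 4)))
  expect_warning(czv <- pearson_matrix(zv, log_transform = FALSE),
                 "zero variance")
  expect_equal(czv[1, 2], 0)
  # few samples warns about degeneracy
  expect_warning(pearson_matrix(lin, log_transform = FALSE), "near-degenerate")
})

test_that("HRR scores equal brute-force mutual rank tables", {
  # hand-checkable 4-gene instance
  cc <- matrix(c(1, .9, .2, .1,
                 .9, 1, .4, .3,
                 .2, .4, 1, .8,
                 .1, .3, .8, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  h <- hrr_matrix(cc)
  expect_equal(h[!diag(4) == 1], hrr_brute(cc)[!diag(4) == 1])
  expect_equal(h["a", "b"], 1L)  # mutual best neighbours
  expect_true(isSymmetric(unname(h)))
  # random instances up to 10 genes
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    m <- matrix(rnorm(n * 5), nrow = n,
                dimnames = list(paste0("g", 1:n), NULL))
    cc <- cor(t(m))
    expect_equal(hrr_matrix(cc), hrr_brute(cc))
  }
  expect_error(hrr_matrix(cc[1:2, 1:2]), "at least 3")
})

test_that("HRR ranking is equivariant under gene relabeling", {
  set.seed(8)
  m <- matrix(rnorm(8 * 5), nrow = 8,
              dimnames = list(paste0("g", 1:8), NULL))
  cc <- cor(t(m))
  h <- hrr_matrix(cc)
  perm <- sample(8)
  hp <- hrr_matrix(cc[perm, perm])
  expect_equal(hp, h[perm, perm])
})

test_that("network construction respects the cutoff and the 1/HRR weights", {
  cc <- matrix(c(1, .9, .2, .1,
                 .9, 1, .4, .3,
                 .2, .4, 1, .8,
                 .1, .3, .8, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  h <- hrr_matrix(cc)
  net <- build_network(h, cc, cutoff = 1)
  expect_equal(nrow(net$edges), 2L)  # only the two mutual-best pairs
  expect_true(all(net$edges$weight * net$edges$hrr == 1))
  # boundary: an HRR of cutoff + 1 is excluded, cutoff itself kept
  h3 <- matrix(c(NA, 31L, 30L,
                 31L, NA, 2L,
                 30L, 2L, NA), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  e3 <- build_network(h3, cutoff = 30)$edges
  expect_equal(nrow(e3), 2L)
  expect_false(any(e3$from == "x" & e3$to == "y"))
  netall <- build_network(h, cc, cutoff = 3)  # n - 1: complete on ranked pairs
  expect_equal(nrow(netall$edges), choose(4, 2))
  # published weight convention at HRR 5 / 15 / 25
  expect_equal(round(1 / c(5, 15, 25), 3), c(0.2, 0.067, 0.04))
  expect_error(build_network(h, cc, cutoff = 0), "at least 1")
})

test_that("raising the cutoff never removes an edge", {
  set.seed(12)
  m <- matrix(rnorm(12 * 4), nrow = 12,
              dimnames = list(paste0("g", 1:12), NULL))
  h <- hrr_matrix(cor(t(m)))
  e5 <- build_network(h, cutoff = 5)$edges
  e9 <- build_network(h, cutoff = 9)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e5) %in% key(e9)))
})

test_that("topology statistics match hand-enumerated graphs", {
  # complete graph K4
  k4 <- t(combn(letters[1:4], 2))
  net <- list(nodes = tibble::tibble(gene_id = letters[1:4]),
              edges = tibble::tibble(from = k4[, 1], to = k4[, 2],
                                     r = NA_real_, hrr = 1L, weight = 1),
              cutoff = 30)
  class(net) <- "coexpression_network"
  st <- network_stats(net)
  expect_equal(st$clustering_coefficient, 1)
  expect_equal(st$density, 1)
  expect_equal(st$diameter, 1)
  # path graph on 4 nodes: distances 1,1,1,2,2,3
  pg <- net
  pg$edges <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d"),
                             r = NA_real_, hrr = 1L, weight = 1)
  stp <- network_stats(pg)
  expect_equal(stp$diameter, 3)
  expect_equal(stp$characteristic_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(stp$clustering_coefficient, 0)
  expect_equal(stp$radius, 2)
  expect_equal(stp$shortest_paths, 12)  # ordered pairs
  # density identities
  expect_equal(stp$density, 2 * 3 / (4 * 3), tolerance = 1e-12)
  expect_equal(stp$density, stp$avg_neighbors / 3, tolerance = 1e-12)
})

test_that("density computed from published-scale node count and mean degree", {
  # a 1296-node graph with mean degree 22.752 has density 0.018 at 3 dp
  expect_equal(round(22.752 / (1296 - 1), 3), 0.018)
})

test_that("within-module HRR is below between-module HRR on planted data", {
  ok <- vapply(1:20, function(s) {
    sim <- simulate_counts(simulation_config(
      n_genes = 60, library_sizes = rep(1e5, 3),
      modules = list(module_spec(15, c(0, 2.5, 2.5), within_noise_sd = 0.2)),
      seed = 300 + s))
    cc <- suppressWarnings(pearson_matrix(compute_rpkm(sim$counts)))
    h <- hrr_matrix(cc)
    members <- rownames(h) %in% sim$truth$module_membership$gene_id
    within <- h[members, members]
    between <- h[members, !members]
    median(within[upper.tri(within)]) < median(between)
  }, logical(1))
  expect_true(all(ok))
})
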