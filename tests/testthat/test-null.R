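test_that("equilibrium null on a single biallelic marker is Bernoulli(1/2)", {
  A <- rbind(P1 = 1L, P2 = 2L)
  panel <- fix_panel(A, pos = 0)
  grid <- build_scan_grid(panel$map, 1)
  null <- equilibrium_null(panel, grid, const1(), const0(), window_cM = 2,
                           n_haplotypes = 2, n_reps = 10000,
                           sparse_min = 1, seed = 4)
  expect_true(all(null$sample %in% c(0, 1)))
  # exact Bernoulli(0.5); 3 s.e. at 1e4 draws
  expect_equal(mean(null$sample), 0.5, tolerance = 3 * 0.005 / 0.5)
})

test_that("null samplers are deterministic under a fixed seed", {
  set.seed(1)
  A <- matrix(sample(1:2, 6 * 30, replace = TRUE), 6, 30)
  rownames(A) <- paste0("P", 1:6)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 10)
  a <- equilibrium_null(panel, grid, window_cM = 10, n_reps = 5, seed = 7)
  b <- equilibrium_null(panel, grid, window_cM = 10, n_reps = 5, seed = 7)
  expect_identical(a$sample, b$sample)
  m1 <- mosaic_null(panel, grid, window_cM = 10, generations = 100,
                    n_reps = 5, seed = 7)
  m2 <- mosaic_null(panel, grid, window_cM = 10, generations = 100,
                    n_reps = 5, seed = 7)
  expect_identical(m1$sample, m2$sample)
  expect_error(equilibrium_null(panel, grid, n_reps = 0), "n_reps")
  expect_error(mosaic_null(panel, grid, generations = -1), "generations")
})

test_that("mosaic sampling with zero generations copies founders exactly", {
  set.seed(2)
  A <- matrix(sample(1:4, 5 * 25, replace = TRUE), 5, 25)
  rownames(A) <- paste0("P", 1:5)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 24)
  null <- mosaic_null(panel, grid, const1(), const0(), window_cM = 48,
                      generations = 0, n_haplotypes = 6, n_reps = 3,
                      sparse_min = 1, seed = 3)
  # every simulated pair score must equal some founder-pair score (or 1)
  founder_scores <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j)
    mean(A[i, ] == A[j, ])))
  ok <- sapply(null$sample, function(s)
    any(abs(s - c(founder_scores, 1)) < 1e-12))
  expect_true(all(ok))
})

test_that("identical founders give a degenerate mosaic null at score 1", {
  A <- matrix(1L, 3, 20)
  rownames(A) <- paste0("P", 1:3)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 19)
  null <- mosaic_null(panel, grid, window_cM = 40, generations = 200,
                      n_reps = 3, sparse_min = 1, seed = 1)
  expect_true(all(abs(null$sample - 1) < 1e-12))
})

test_that("empirical threshold is the inverse-CDF order statistic", {
  null <- structure(list(sample = seq(0.1, 1, by = 0.1),
                         sampler = "equilibrium"),
                    class = "null_distribution")
  expect_equal(empirical_threshold(null, 0.1)$value, 0.9)
  expect_equal(empirical_threshold(null, 0.5)$value, 0.5)
  # monotone: smaller alpha, larger threshold
  set.seed(8)
  s <- runif(500)
  null2 <- structure(list(sample = s, sampler = "equilibrium"),
                     class = "null_distribution")
  th <- sapply(c(0.2, 0.1, 0.05, 0.01), function(a)
    empirical_threshold(null2, a)$value)
  expect_true(all(diff(th) >= 0))
  expect_error(empirical_threshold(null2, 0), "alpha")
  expect_error(
    empirical_threshold(structure(list(sample = numeric(0)),
                                  class = "null_distribution"), 0.1),
    "empty")
})

test_that("equilibrium threshold <= mosaic threshold on a redundant map", {
  # co-located and monomorphic markers cannot be shuffled apart by the
  # mosaic process, which keeps mosaic scores higher
  set.seed(31)
  pos <- rep(seq(0, 40, by = 10), each = 3)  # co-located triplets
  A <- matrix(sample(1:2, 8 * length(pos), replace = TRUE), 8, length(pos))
  A[, 1:3] <- 1L  # monomorphic block
  rownames(A) <- paste0("P", 1:8)
  panel <- fix_panel(A, pos = pos)
  grid <- build_scan_grid(panel$map, 10)
  wins <- 0
  for (sd in 1:5) {
    eq <- empirical_threshold(
      equilibrium_null(panel, grid, window_cM = 20, n_reps = 30,
                       sparse_min = 5, seed = sd), 0.05)$value
    mo <- empirical_threshold(
      mosaic_null(panel, grid, window_cM = 20, generations = 500,
                  n_reps = 30, sparse_min = 5, seed = sd), 0.05)$value
    wins <- wins + (eq <= mo)
  }
  expect_gte(wins, 4)
})

test_that("mosaic threshold is non-increasing in generations", {
  set.seed(17)
  A <- matrix(sample(1:2, 10 * 60, replace = TRUE), 10, 60)
  # make founders related: copy blocks to create long shared segments
  A[2, 1:30] <- A[1, 1:30]; A[4, 20:50] <- A[3, 20:50]
  rownames(A) <- paste0("P", 1:10)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 10)
  th <- sapply(c(0, 50, 500), function(ng)
    empirical_threshold(
      mosaic_null(panel, grid, window_cM = 20, generations = ng,
                  n_reps = 40, sparse_min = 5, seed = 9), 0.05)$value)
  expect_true(all(diff(th) <= 1e-9))
})
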