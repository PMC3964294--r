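test_that("dosage blocks follow the genotype-probability expectation", {
  # one F2 family of three individuals: certain het, certain ii, and an
  # all-missing individual whose prior gives dosages (1, 1)
  cm <- fix_map(c(0, 20))
  fam <- data.frame(id = "D1", parent_i = "A", parent_j = "B", type = "F2")
  G <- rbind(c(1L, 1L), c(0L, 0L), c(NA, NA))
  design <- cross_design(fam, list(D1 = G), cm, c("A", "B"))
  grid <- build_scan_grid(cm, 20)
  probs <- suppressWarnings(genotype_probabilities(design, grid))
  blk <- design_matrix(probs, 1)
  expect_equal(blk$dosage[1, ], c(1, 1))   # heterozygote: one of each
  expect_equal(blk$dosage[2, ], c(2, 0))   # ii homozygote
  expect_equal(blk$dosage[3, ], c(1, 1))   # prior (1/4, 1/2, 1/4)
  expect_true(all(abs(rowSums(blk$dosage) - 2) < 1e-9))
})

test_that("clustering collapses parent dosages into class dosages", {
  cm <- fix_map(c(0, 20))
  fam <- data.frame(id = c("D1", "D2"),
                    parent_i = c("A", "A"), parent_j = c("B", "C"),
                    type = "F2")
  G1 <- rbind(c(1L, 1L), c(0L, 2L))
  G2 <- rbind(c(2L, 2L))
  design <- cross_design(fam, list(D1 = G1, D2 = G2), cm, c("A", "B", "C"))
  grid <- build_scan_grid(cm, 20)
  probs <- genotype_probabilities(design, grid)
  lc <- local_clustering(grid$loci,
                         matrix(c(1L, 1L, 2L), nrow(grid$loci), 3,
                                byrow = TRUE,
                                dimnames = list(NULL, c("A", "B", "C"))))
  blk <- design_matrix(probs, 1, lc)
  expect_equal(blk$n_classes, 2)
  # family D1 crosses two members of the same class: dosage always 2
  expect_equal(blk$dosage[1:2, 1], c(2, 2))
  # family D2 (A x C) splits between the classes
  expect_equal(blk$dosage[3, ], c(0, 2))
})

test_that("F-test matches an explicit projection-matrix OLS oracle", {
  proj <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  set.seed(14)
  for (k in 1:20) {
    n <- sample(20:40, 1)
    p0 <- sample(2:4, 1); p1 <- sample(1:3, 1)
    X0 <- cbind(1, matrix(rnorm(n * (p0 - 1)), n))
    X1 <- matrix(rnorm(n * p1), n)
    y <- rnorm(n)
    got <- fit_and_test(y, X0, X1)
    P0 <- proj(X0); P1 <- proj(cbind(X0, X1))
    rss0 <- sum((y - P0 %*% y)^2)
    rss1 <- sum((y - P1 %*% y)^2)
    Fo <- ((rss0 - rss1) / p1) / (rss1 / (n - p0 - p1))
    po <- pf(Fo, p1, n - p0 - p1, lower.tail = FALSE)
    expect_equal(got$F, Fo, tolerance = 1e-10)
    expect_equal(got$p, po, tolerance = 1e-10)
    expect_equal(got$df1, p1)
  }
})

test_that("rank-deficient locus terms reduce df1; empty terms skip the test", {
  set.seed(15)
  n <- 30
  X0 <- cbind(1, rnorm(n))
  x <- rnorm(n)
  X1 <- cbind(x, 2 * x)   # rank 1
  got <- fit_and_test(rnorm(n), X0, X1)
  expect_equal(got$df1, 1L)
  skip <- fit_and_test(rnorm(n), X0, matrix(0, n, 0))
  expect_equal(skip$neglog10p, 0)
  expect_equal(skip$p, 1)
})

test_that("all-singleton clustering reproduces the connected scan exactly", {
  bench <- small_bench()
  ds <- bench_data(bench, qtl = NULL, seed = 30)
  singles <- local_clustering(
    bench$grid$loci,
    matrix(rep(seq_along(bench$panel$parents), each = nrow(bench$grid$loci)),
           nrow(bench$grid$loci),
           dimnames = list(NULL, bench$panel$parents)))
  sc_conn <- qtl_scan(ds$y, ds$probs)
  sc_ld <- qtl_scan(ds$y, ds$probs, singles)
  expect_equal(sc_ld$F, sc_conn$F, tolerance = 0)
  expect_equal(sc_ld$p, sc_conn$p, tolerance = 0)
  expect_equal(sc_ld$df1, sc_conn$df1)
  expect_equal(sc_ld$df2, sc_conn$df2)
})

test_that("a locus with one ancestral-allele class is skipped in the scan", {
  bench <- small_bench()
  ds <- bench_data(bench, qtl = NULL, seed = 31)
  ones <- local_clustering(
    bench$grid$loci,
    matrix(1L, nrow(bench$grid$loci), length(bench$panel$parents),
           dimnames = list(NULL, bench$panel$parents)))
  sc <- qtl_scan(ds$y, ds$probs, ones)
  expect_true(all(sc$neglog10p == 0))
  expect_true(all(sc$n_classes == 1))
})

test_that("a strong QTL is essentially always detected above threshold", {
  bench <- small_bench()
  tq <- which.min(abs(bench$grid$loci$pos - 30))
  mutant <- setNames(bench$panel$parents %in%
                       bench$panel$parents[c(1, 3, 5)],
                     bench$panel$parents)
  for (sd in 1:5) {
    ds <- bench_data(bench,
                     qtl = list(chrom = "chr1",
                                pos = bench$grid$loci$pos[tq],
                                effect = 1, mutant = mutant),
                     seed = 100 + sd)
    sc <- qtl_scan(ds$y, ds$probs)
    expect_gt(max(sc$neglog10p), 3)
  }
})

test_that("permutation thresholds are reproducible and monotone in alpha", {
  bench <- small_bench()
  ds <- bench_data(bench, qtl = NULL, seed = 32)
  t1 <- permutation_threshold(ds$y, ds$probs, n_perm = 50, alpha = 0.1,
                              seed = 9)
  t2 <- permutation_threshold(ds$y, ds$probs, n_perm = 50, alpha = 0.1,
                              seed = 9)
  expect_identical(t1$threshold, t2$threshold)
  t3 <- permutation_threshold(ds$y, ds$probs, n_perm = 50, alpha = 0.25,
                              seed = 9)
  expect_lte(t3$threshold, t1$threshold)
})

test_that("the LD threshold tends to exceed the connected threshold", {
  bench <- small_bench()
  wins <- 0
  for (sd in 1:5) {
    ds <- bench_data(bench, qtl = NULL, seed = 300 + sd)
    tc <- permutation_threshold(ds$y, ds$probs, NULL, n_perm = 60,
                                seed = sd)$threshold
    tl <- permutation_threshold(ds$y, ds$probs, bench$clustering,
                                n_perm = 60, seed = sd)$threshold
    wins <- wins + (tl >= tc)
  }
  expect_gte(wins, 4)
})
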