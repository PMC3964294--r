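test_that("zero mosaic generations copy ancestors verbatim", {
  sim <- simulate_parent_panel(n_ancestors = 3, n_parents = 6,
                               generations = 0, seed = 4)
  for (h in seq_len(6)) {
    expect_equal(length(unique(sim$truth[h, ])), 1L)
    expect_equal(unname(sim$panel$alleles[h, ]),
                 sim$ancestors[sim$truth[h, 1], ])
  }
})

test_that("a single ancestor makes all parents identical", {
  sim <- simulate_parent_panel(n_ancestors = 1, n_parents = 5, seed = 5)
  expect_true(all(apply(sim$panel$alleles, 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("panel simulation is reproducible under a fixed seed", {
  a <- simulate_parent_panel(seed = 6)
  b <- simulate_parent_panel(seed = 6)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$truth, b$truth)
})

test_that("ancestor switch rate follows the Poisson break process", {
  # adjacent markers step cM apart change ancestor with probability
  # (1 - exp(-generations * step / 100)) * (n_anc - 1) / n_anc
  ng <- 40; n_anc <- 4
  sim <- simulate_parent_panel(n_ancestors = n_anc, n_parents = 100,
                               chr_length_cM = 100, marker_step_cM = 1,
                               generations = ng, seed = 7)
  tr <- sim$truth
  sw <- mean(tr[, -1] != tr[, -ncol(tr)])
  p_exp <- (1 - exp(-ng / 100)) * (n_anc - 1) / n_anc
  expect_equal(sw, p_exp, tolerance = 0.05)
})

test_that("QTL alleles go to the biggest class, ties broken reproducibly", {
  loci <- data.frame(chrom = "1", pos = 1)
  a <- matrix(c(1L, 2L, 2L, 3L), 1, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  lc <- local_clustering(loci, a)
  m <- assign_qtl_alleles(lc, 1)
  expect_equal(names(m)[m], c("B", "C"))

  tie <- local_clustering(loci, matrix(c(1L, 1L, 2L, 2L), 1, 4,
                                       dimnames = list(NULL, LETTERS[1:4])))
  m1 <- assign_qtl_alleles(tie, 1, seed = 3)
  m2 <- assign_qtl_alleles(tie, 1, seed = 3)
  expect_identical(m1, m2)
  expect_true(sum(m1) == 2)

  singles <- local_clustering(loci, matrix(1:4, 1, 4,
                                           dimnames = list(NULL, LETTERS[1:4])))
  ms <- assign_qtl_alleles(singles, 1, seed = 2)
  expect_equal(sum(ms), 1)
})

test_that("phenotypes are calibrated N(0,1) plus the additive QTL", {
  bench <- small_bench()
  big <- bench$fam_table
  big$n <- 500
  # no QTL: pure standard normal noise
  d0 <- simulate_family_data(big, bench$panel, bench$consensus_map,
                             qtl = NULL, seed = 8)
  expect_equal(var(d0$pheno), 1, tolerance = 0.1)
  expect_equal(mean(d0$pheno), 0, tolerance = 0.1)

  parents <- bench$panel$parents
  # a fully segregating F2 family: variance 1 + a^2/2
  tq <- which.min(abs(bench$grid$loci$pos - 30))
  fam1 <- big[1, , drop = FALSE]; fam1$n <- 4000
  mut <- setNames(parents == fam1$parent_i, parents)
  a_eff <- 1
  d1 <- simulate_family_data(fam1, bench$panel, bench$consensus_map,
                             qtl = list(chrom = "chr1",
                                        pos = bench$grid$loci$pos[tq],
                                        effect = a_eff, mutant = mut),
                             seed = 9)
  expect_equal(var(d1$pheno), 1 + a_eff^2 / 2, tolerance = 0.12)

  # both parents mutant: a constant shift of 2a, no extra variance
  mut2 <- setNames(rep(TRUE, length(parents)), parents)
  d2 <- simulate_family_data(fam1, bench$panel, bench$consensus_map,
                             qtl = list(chrom = "chr1",
                                        pos = bench$grid$loci$pos[tq],
                                        effect = 0.5, mutant = mut2),
                             seed = 10)
  expect_equal(mean(d2$pheno), 1, tolerance = 0.1)
  expect_equal(var(d2$pheno), 1, tolerance = 0.1)
})

test_that("precision counts detections by surrounding interval", {
  # always exactly on target (two positions, two replicates each)
  det_exact <- list(list(10, 10), list(55, 55))
  truth <- c(10, 55)
  r <- evaluate_detections(list(connected = det_exact, ld = det_exact),
                           truth)
  expect_true(all(r$precision == 100))
  expect_true(all(r$power == 100))

  # 3 cM off: inside the 5 and 10 cM intervals only
  det_off <- list(list(13), list(58))
  truth2 <- c(10, 55)
  r2 <- evaluate_detections(list(connected = det_off, ld = det_off), truth2)
  expect_equal(unname(r2$precision[1, ]), c(0, 0, 100, 100))

  # no detections at all: power zero, precision missing
  det_none <- list(list(numeric(0)))
  r3 <- evaluate_detections(list(connected = det_none, ld = det_none),
                            c(10))
  expect_equal(unname(r3$power), c(0, 0))
  expect_true(all(is.nan(r3$precision)))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (k in 1:10) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2L, 3L, 4L, 5L, 1L)), 1)
})
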