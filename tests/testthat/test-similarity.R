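test_that("window_markers returns in-window markers with distances", {
  m <- fix_map(c(0, 5, 10, 15, 20))
  wm <- window_markers(m, "1", 10, 20)
  expect_equal(nrow(wm), 5)
  expect_equal(wm$dist, c(10, 5, 0, 5, 10))

  wm2 <- window_markers(m, "1", 0, 10)
  expect_equal(wm2$pos, c(0, 5))

  expect_equal(nrow(window_markers(m, "1", 100, 10)), 0)
})

test_that("similarity score matches hand-computed sums and segments", {
  hi <- c(1, 1, 1, 1, 1)
  hj <- c(1, 0, 1, 1, 0)
  dist <- c(10, 5, 0, 5, 10)
  w1 <- const1(); w0 <- const0()
  # alike-in-state part only: 3 matches of 5
  r <- li_jiang_score(hi, hj, dist, w1, w0)
  expect_equal(r$s, 3)
  expect_equal(r$s_map, 5)
  expect_equal(r$s_tilde, 0.6)
  # segment part only: the center-spanning run covers markers 3 and 4
  r2 <- li_jiang_score(hi, hj, dist, w0, w1)
  expect_equal(r2$s, 2)
  expect_equal(r2$s_tilde, 0.4)
  # self-similarity is exactly 1 whatever the weights
  for (k in c("exponential", "gaussian", "uniform_density"))
    expect_equal(li_jiang_score(hi, hi, dist,
                                make_weight_function(k, 20),
                                make_weight_function("uniform_density", 20))$s_tilde,
                 1)
})

test_that("missing-data policies act on the alike-in-state sum as documented", {
  hi <- c(1, NA, 1)
  hj <- c(1, 1, 0)
  dist <- c(1, 0, 1)
  w1 <- const1(); w0 <- const0()
  # w1 sum: true counts the missing comparison, false/non_assigned do not
  expect_equal(li_jiang_score(hi, hj, dist, w1, w0, "true")$s, 2)
  expect_equal(li_jiang_score(hi, hj, dist, w1, w0, "false")$s, 1)
  expect_equal(li_jiang_score(hi, hj, dist, w1, w0, "non_assigned")$s, 1)
})

test_that("missing at the window center: false kills the segment, non_assigned skips it", {
  hi <- c(1, 1, NA, 1, 1)
  hj <- c(1, 1, 2, 1, 0)
  dist <- c(2, 1, 0, 1, 2)
  w0 <- const0(); w1 <- const1()
  # false: comparison at the center is false -> empty segment
  expect_equal(li_jiang_score(hi, hj, dist, w0, w1, "false")$s, 0)
  # true: center counts as a match, run spans markers 1-4
  expect_equal(li_jiang_score(hi, hj, dist, w0, w1, "true")$s, 4)
  # non_assigned: segment starts at the informative neighbour of the
  # center; the runs on each side are markers 1-2 and marker 4
  expect_equal(li_jiang_score(hi, hj, dist, w0, w1, "non_assigned")$s, 2)
})

test_that("reliability weight follows the sparse-window rule", {
  # all windows dense
  expect_equal(reliability_weight(c(3, 4, 5), c(12, 15, 20), 10), c(1, 1, 1))
  # sparse windows normalized by the sparse maximum
  expect_equal(reliability_weight(c(2, 4, 9), c(3, 5, 12), 10),
               c(0.5, 1, 1))
  # empty window
  expect_equal(reliability_weight(c(0, 4), c(0, 3), 10), c(0, 1))
})

test_that("extended score is the convex combination of score and kinship", {
  expect_equal(extended_score(0.5, 0.9, 1), 0.5)
  expect_equal(extended_score(0.5, 0.9, 0), 0.9)
  expect_equal(extended_score(0.5, 0.9, 0.6), 0.66)
})

test_that("similarity_scan matches an independent per-locus loop oracle", {
  set.seed(11)
  np <- 4; M <- 50
  A <- matrix(sample(1:2, np * M, replace = TRUE), np, M)
  A[sample(length(A), 30)] <- NA
  rownames(A) <- paste0("P", 1:np)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 7)
  W <- 14
  w1 <- make_weight_function("exponential", W)
  w2 <- make_weight_function("uniform_density", W)
  K <- default_kinship(panel)
  field <- similarity_scan(panel, grid, w1, w2, W, na_policy = "true",
                           sparse_min = 10)

  # oracle: recompute every pair at every locus with li_jiang_score, then
  # apply the sparse reliability rule by hand
  nm <- sapply(seq_len(nrow(grid$loci)), function(t)
    nrow(window_markers(panel$map, grid$loci$chrom[t], grid$loci$pos[t], W)))
  smap <- sapply(seq_len(nrow(grid$loci)), function(t) {
    wm <- window_markers(panel$map, grid$loci$chrom[t], grid$loci$pos[t], W)
    sum(w1(wm$dist)) + sum(w2(wm$dist))
  })
  P <- rep(1, length(nm))
  if (any(nm < 10)) P[nm < 10] <- smap[nm < 10] / max(smap[nm < 10])
  for (t in seq_len(nrow(grid$loci))) {
    wm <- window_markers(panel$map, grid$loci$chrom[t], grid$loci$pos[t], W)
    for (pr in seq_len(nrow(field$pairs))) {
      i <- field$pairs$i[pr]; j <- field$pairs$j[pr]
      lj <- li_jiang_score(A[i, wm$idx], A[j, wm$idx], wm$dist, w1, w2,
                           "true")
      want <- P[t] * lj$s_tilde + (1 - P[t]) * K[i, j]
      expect_equal(field$S[t, pr], want, tolerance = 1e-12)
    }
  }
})

test_that("similarity field respects its invariants", {
  set.seed(12)
  A <- matrix(sample(1:3, 6 * 40, replace = TRUE), 6, 40)
  rownames(A) <- paste0("P", 1:6)
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 5)
  field <- similarity_scan(panel, grid, window_cM = 10, sparse_min = 5)
  expect_true(all(field$S >= -1e-12 & field$S <= 1 + 1e-12))
  # identical parents score 1 everywhere
  A2 <- rbind(P1 = A[1, ], P2 = A[1, ], P3 = A[3, ])
  f2 <- similarity_scan(fix_panel(A2), grid, window_cM = 10, sparse_min = 5)
  expect_equal(unname(f2$S[, 1]), rep(1, nrow(grid$loci)))
})

test_that("constant-1 w1 with complete data gives the alike-in-state share", {
  set.seed(13)
  A <- matrix(sample(1:2, 2 * 30, replace = TRUE), 2, 30)
  rownames(A) <- c("P1", "P2")
  panel <- fix_panel(A)
  grid <- build_scan_grid(panel$map, 29)
  f <- similarity_scan(panel, grid, const1(), const0(), window_cM = 58,
                       kinship = diag(2), sparse_min = 1)
  t_mid <- which.min(abs(grid$loci$pos - 14.5))
  expect_equal(f$s_tilde[t_mid, 1], mean(A[1, ] == A[2, ]))
})
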