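#' Markers inside a sliding window
#'
#' All markers of a chromosome whose distance to the window center `t`
#' is at most half the window length, with their distances.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name.
#' @param t window center (cM, on `map`'s coordinate system).
#' @param window_cM window length L; markers with `|pos - t| <= L/2` are
#'   returned.
#' @return data frame with columns `idx` (row index in `map$markers`),
#'   `marker`, `pos`, `dist`; possibly zero rows.
#' @export
window_markers <- function(map, chrom, t, window_cM) {
  sel <- which(map$markers$chrom == chrom &
                 abs(map$markers$pos - t) <= window_cM / 2 + 1e-9)
  data.frame(idx = sel,
             marker = map$markers$marker[sel],
             pos = map$markers$pos[sel],
             dist = abs(map$markers$pos[sel] - t),
             stringsAsFactors = FALSE)
}

# ---- internal scoring engine -------------------------------------------

# Precompute, for each scan locus, the window marker set, evaluated
# weights, center-candidate indices and the complete-data self-similarity
# s_map.  `loci` is a data frame (chrom, pos) of window centers already on
# the parent-map coordinate system.
window_plan <- function(map, loci, w1, w2, window_cM, sparse_min) {
  plans <- vector("list", nrow(loci))
  s_map <- numeric(nrow(loci))
  n_mark <- integer(nrow(loci))
  for (t in seq_len(nrow(loci))) {
    wm <- window_markers(map, loci$chrom[t], loci$pos[t], window_cM)
    if (nrow(wm) == 0) {
      plans[[t]] <- list(idx = integer(0))
      next
    }
    w1v <- w1(wm$dist)
    w2v <- w2(wm$dist)
    cand <- which(wm$dist <= min(wm$dist) + 1e-9)
    plans[[t]] <- list(idx = wm$idx, w1v = w1v, w2v = w2v, cand = cand)
    s_map[t] <- sum(w1v) + sum(w2v)
    n_mark[t] <- nrow(wm)
  }
  sparse <- n_mark < sparse_min
  P <- reliability_weight(s_map, n_mark, sparse_min)
  list(plans = plans, s_map = s_map, n_markers = n_mark,
       sparse = sparse, P = P)
}

#' Reliability weight of the similarity score
#'
#' Windows holding at least `sparse_min` markers are considered dense and
#' get full reliability P = 1.  Sparse windows get
#' `P = s_map / max(s_map over sparse windows)`, so the locally computed
#' similarity is shaded toward the kinship prior exactly where marker
#' information is thin.  An empty window has `s_map = 0` hence P = 0.
#'
#' @param s_map numeric vector of per-locus self-similarities.
#' @param n_markers integer vector of per-window marker counts.
#' @param sparse_min windows with fewer markers than this are sparse.
#' @return numeric vector of P in \[0, 1\].
#' @export
reliability_weight <- function(s_map, n_markers, sparse_min) {
  stopifnot(length(s_map) == length(n_markers))
  P <- rep(1, length(s_map))
  sparse <- n_markers < sparse_min
  if (any(sparse)) {
    smax <- max(s_map[sparse])
    P[sparse] <- if (smax > 0) s_map[sparse] / smax else 0
  }
  P
}

#' Blend local similarity with the kinship prior
#'
#' The extended score is the convex combination
#' `S = P * s_tilde + (1 - P) * K`, elementwise.
#'
#' @param s_tilde normalized similarity (scalar, vector or matrix in
#'   \[0, 1\]).
#' @param K kinship of the same shape.
#' @param P reliability weight(s) in \[0, 1\].
#' @return same shape as `s_tilde`.
#' @export
extended_score <- function(s_tilde, K, P) {
  P * s_tilde + (1 - P) * K
}

# map comparison NA per policy: "true" -> match, "false"/"non_assigned"
# -> no weight for w1. Returns {TRUE, FALSE, NA} matrix for segment use.
.cmp_matrix <- function(A, idx, ii, jj) {
  ai <- A[ii, idx, drop = FALSE]
  aj <- A[jj, idx, drop = FALSE]
  ai == aj   # NA where either is missing
}

# w2 segment sum for all pairs at one locus. cmp has no NA.
.segment_sum <- function(cmp, w2v, cand) {
  K <- ncol(cmp)
  best <- numeric(nrow(cmp))
  for (cc in cand) {
    tot <- w2v[cc] * cmp[, cc]
    R <- cmp[, cc]
    if (cc < K) for (k in (cc + 1):K) {
      R <- R & cmp[, k]
      if (!any(R)) break
      tot <- tot + w2v[k] * R
    }
    R <- cmp[, cc]
    if (cc > 1) for (k in (cc - 1):1) {
      R <- R & cmp[, k]
      if (!any(R)) break
      tot <- tot + w2v[k] * R
    }
    best <- pmax(best, tot)
  }
  best
}

# Scalar segment sum under the non-assigned policy: missing comparisons
# break the common segment everywhere except at the window center, where
# they are skipped until the first informative marker on each side.
.segment_sum_na <- function(m, w2v, cand) {
  K <- length(m)
  seeds <- integer(0)
  for (cc in cand) {
    if (!is.na(m[cc])) {
      seeds <- c(seeds, cc)
    } else {
      r <- cc; while (r <= K && is.na(m[r])) r <- r + 1
      l <- cc; while (l >= 1 && is.na(m[l])) l <- l - 1
      if (r <= K) seeds <- c(seeds, r)
      if (l >= 1) seeds <- c(seeds, l)
    }
  }
  best <- 0
  for (s in unique(seeds)) {
    if (is.na(m[s]) || !m[s]) next
    l <- s; while (l > 1 && isTRUE(m[l - 1])) l <- l - 1
    r <- s; while (r < K && isTRUE(m[r + 1])) r <- r + 1
    best <- max(best, sum(w2v[l:r]))
  }
  best
}

# scores for all pairs at one locus; returns raw s vector (length npairs)
.locus_scores <- function(A, plan, ii, jj, policy) {
  cmp <- .cmp_matrix(A, plan$idx, ii, jj)
  has_na <- anyNA(cmp)
  if (policy == "true") {
    if (has_na) cmp[is.na(cmp)] <- TRUE
    s1 <- as.vector(cmp %*% plan$w1v)
    s2 <- .segment_sum(cmp, plan$w2v, plan$cand)
  } else if (policy == "false") {
    if (has_na) cmp[is.na(cmp)] <- FALSE
    s1 <- as.vector(cmp %*% plan$w1v)
    s2 <- .segment_sum(cmp, plan$w2v, plan$cand)
  } else { # non_assigned: skip missing in the w1 sum; center-skip for w2
    cmp0 <- cmp
    cmp0[is.na(cmp0)] <- FALSE
    s1 <- as.vector(cmp0 %*% plan$w1v)
    if (!has_na) {
      s2 <- .segment_sum(cmp0, plan$w2v, plan$cand)
    } else {
      s2 <- vapply(seq_len(nrow(cmp)), function(p)
        .segment_sum_na(cmp[p, ], plan$w2v, plan$cand), numeric(1))
    }
  }
  s1 + s2
}

#' Sliding-window similarity score for one haplotype pair
#'
#' The score sums, over the markers of the window, a weight `w1` for each
#' alike-in-state allele comparison plus a weight `w2` for each marker of
#' the longest common segment, defined as the maximal run of consecutive
#' alike-in-state window markers containing the marker(s) nearest to the
#' window center.  It is normalized by the complete-data self-similarity
#' `s_map` of the window, so it does not grow with window length or
#' marker density.
#'
#' @param hi,hj integer allele vectors (one per haplotype) covering the
#'   window markers, `NA` = missing.
#' @param dist distances of the window markers to the window center.
#' @param w1,w2 weight functions from [make_weight_function()].
#' @param na_policy `"true"` (missing comparisons count as matches,
#'   default), `"false"` (count as mismatches) or `"non_assigned"`
#'   (contribute no weight; segment rule treats missing at the window
#'   center as transparent).
#' @return list with elements `s`, `s_map`, `s_tilde`.
#' @export
li_jiang_score <- function(hi, hj, dist, w1, w2,
                           na_policy = c("true", "false", "non_assigned")) {
  na_policy <- match.arg(na_policy)
  stopifnot(length(hi) == length(hj), length(hi) == length(dist))
  if (length(hi) == 0) stop("empty window: score undefined")
  w1v <- w1(dist); w2v <- w2(dist)
  cand <- which(dist <= min(dist) + 1e-9)
  plan <- list(idx = seq_along(hi), w1v = w1v, w2v = w2v, cand = cand)
  A <- rbind(as.integer(hi), as.integer(hj))
  s <- .locus_scores(A, plan, 1L, 2L, na_policy)
  s_map <- sum(w1v) + sum(w2v)
  list(s = s, s_map = s_map,
       s_tilde = if (s_map > 0) s / s_map else NA_real_)
}

#' Genome-wide extended similarity scan
#'
#' Computes the kinship-extended similarity score for every pair of
#' parent lines at every scan locus, sliding a window of `window_cM`
#' centimorgans along the parent map.  Scan loci live on the consensus
#' map; when an `alignment` is given they are transferred to the parent
#' map (and clamped to its anchored range) before the window is read.
#'
#' @param panel a [haplotype_panel()].
#' @param grid a [build_scan_grid()] result (consensus coordinates).
#' @param w1,w2 weight functions ([make_weight_function()]); defaults are
#'   exponential / uniform density.
#' @param window_cM window length in cM (default 20).
#' @param na_policy missing-data policy, see [li_jiang_score()].
#' @param kinship optional parent x parent kinship matrix; defaults to
#'   the whole-genome alike-in-state kinship ([default_kinship()]).  Use
#'   an identity matrix to model independent haplotypes.
#' @param sparse_min windows with fewer markers are down-weighted toward
#'   the kinship prior (default 10); see [reliability_weight()].
#' @param alignment optional [align_maps()] result linking the consensus
#'   map to the panel's map.
#' @return An object of class `similarity_field`: `loci` (consensus
#'   chrom/pos), `pairs` (index table), `S` (loci x pairs extended
#'   scores), `s_tilde`, `s_map`, `P`, `n_markers`, `parents`, `kinship`.
#' @export
similarity_scan <- function(panel, grid,
                            w1 = make_weight_function("exponential", window_cM),
                            w2 = make_weight_function("uniform_density", window_cM),
                            window_cM = 20,
                            na_policy = c("true", "false", "non_assigned"),
                            kinship = NULL, sparse_min = 10,
                            alignment = NULL) {
  na_policy <- match.arg(na_policy)
  if (is.null(kinship)) kinship <- default_kinship(panel)
  parents <- panel$parents
  stopifnot(identical(dim(kinship), c(length(parents), length(parents))))
  loci <- grid$loci
  ploci <- transfer_grid(loci, alignment, panel$map)
  wp <- window_plan(panel$map, ploci, w1, w2, window_cM, sparse_min)
  np <- length(parents)
  pr <- pair_index(np)
  Kv <- kinship[cbind(pr$i, pr$j)]
  A <- panel$alleles
  nt <- nrow(loci)
  s_tilde <- matrix(NA_real_, nt, nrow(pr))
  S <- matrix(NA_real_, nt, nrow(pr))
  for (t in seq_len(nt)) {
    plan <- wp$plans[[t]]
    if (length(plan$idx) == 0) {
      S[t, ] <- Kv  # P = 0: fall back on the kinship prior
      next
    }
    s <- .locus_scores(A, plan, pr$i, pr$j, na_policy)
    st <- s / wp$s_map[t]
    s_tilde[t, ] <- st
    S[t, ] <- extended_score(st, Kv, wp$P[t])
  }
  structure(list(loci = loci, pairs = pr, S = S, s_tilde = s_tilde,
                 s_map = wp$s_map, P = wp$P, n_markers = wp$n_markers,
                 parents = parents, kinship = kinship,
                 config = list(w1 = attr(w1, "kind"), w2 = attr(w2, "kind"),
                               window_cM = window_cM, na_policy = na_policy,
                               sparse_min = sparse_min)),
            class = "similarity_field")
}

# transfer grid loci (consensus coords) onto the parent map, clamping to
# the chromosome's marker span so every scan locus gets a window
transfer_grid <- function(loci, alignment, parent_map) {
  out <- loci
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    p <- if (is.null(alignment)) loci$pos[sel]
         else transfer_position(alignment, ch, loci$pos[sel], "consensus")
    rng <- range(parent_map$markers$pos[parent_map$markers$chrom == ch])
    out$pos[sel] <- pmin(pmax(p, rng[1]), rng[2])
  }
  out
}

pair_index <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = ij[, "row"], j = ij[, "col"])[order(ij[, "row"], ij[, "col"]), ]
}

#' Extract the symmetric similarity matrix at one scan locus
#'
#' @param field a [similarity_scan()] result.
#' @param t locus row index in `field$loci`.
#' @return symmetric parent x parent matrix with unit diagonal.
#' @export
similarity_matrix <- function(field, t) {
  np <- length(field$parents)
  M <- diag(1, np)
  dimnames(M) <- list(field$parents, field$parents)
  M[cbind(field$pairs$i, field$pairs$j)] <- field$S[t, ]
  M[cbind(field$pairs$j, field$pairs$i)] <- field$S[t, ]
  M
}

#' @export
print.similarity_field <- function(x, ...) {
  cat("Similarity field:", nrow(x$loci), "loci x", nrow(x$pairs),
      "parent pairs\n")
  cat(sprintf("  w1=%s, w2=%s, window %g cM, na.replace=%s\n",
              x$config$w1, x$config$w2, x$config$window_cM,
              x$config$na_policy))
  cat(sprintf("  sparse windows: %d of %d\n",
              sum(x$n_markers < x$config$sparse_min), nrow(x$loci)))
  invisible(x)
}
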