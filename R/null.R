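#' Null distributions of the similarity score
#'
#' Both samplers simulate sets of unrelated haplotypes on the parent map,
#' score every pair at every scan locus with the same window, weights and
#' missing-data policy as the real analysis, and pool all scores into an
#' empirical null distribution.  During simulation the kinship is the
#' identity matrix, which models the independence of the simulated
#' haplotypes; the extended score of a pair is then `P * s_tilde`.
#'
#' `equilibrium_null` draws each marker independently, uniformly over the
#' alleles observed at that marker in the panel (linkage equilibrium with
#' equifrequent alleles).  `mosaic_null` mimics the evolution of an
#' isolated population founded by the panel haplotypes: each simulated
#' chromosome receives `B ~ Poisson(N_G * L_c)` crossover breaks (`L_c`
#' chromosome length in Morgans over `N_G` generations), break positions
#' uniform along the chromosome, and each inter-break block copies the
#' marker alleles of a uniformly drawn founder.
#'
#' @param panel a [haplotype_panel()]; for the equilibrium sampler it
#'   supplies the per-marker allele catalogue, for the mosaic sampler the
#'   founder haplotypes.
#' @param grid a [build_scan_grid()] (consensus coordinates).
#' @param w1,w2,window_cM,na_policy,sparse_min,alignment as in
#'   [similarity_scan()].
#' @param n_haplotypes number of haplotypes per repetition (default: the
#'   panel size).
#' @param n_reps number of simulated haplotype sets (default 200).
#' @param generations `N_G`, the number of generations of the mosaic
#'   process (default 500, at which the threshold has converged in
#'   typical designs).
#' @param seed integer seed for reproducibility.
#' @return An object of class `null_distribution`: `sample` (pooled
#'   scores in \[0, 1\]), `sampler`, `n_reps`, `seed` (+ `generations`
#'   for the mosaic sampler).
#' @export
equilibrium_null <- function(panel, grid,
                             w1 = make_weight_function("exponential", window_cM),
                             w2 = make_weight_function("uniform_density", window_cM),
                             window_cM = 20,
                             na_policy = "true",
                             n_haplotypes = length(panel$parents),
                             n_reps = 200, sparse_min = 10,
                             alignment = NULL, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  catalogue <- apply(panel$alleles, 2, function(a) unique(a[!is.na(a)]),
                     simplify = FALSE)
  catalogue <- lapply(catalogue, function(a) if (length(a) == 0) 0L else a)
  M <- ncol(panel$alleles)
  draw <- function() {
    A <- matrix(0L, n_haplotypes, M)
    for (k in seq_len(M)) {
      alle <- catalogue[[k]]
      A[, k] <- if (length(alle) == 1) alle else
        sample(alle, n_haplotypes, replace = TRUE)
    }
    A
  }
  .pooled_null(panel, grid, w1, w2, window_cM, na_policy, sparse_min,
               alignment, draw, n_reps, seed,
               sampler = "equilibrium")
}

#' @rdname equilibrium_null
#' @export
mosaic_null <- function(panel, grid,
                        w1 = make_weight_function("exponential", window_cM),
                        w2 = make_weight_function("uniform_density", window_cM),
                        window_cM = 20,
                        na_policy = "true",
                        generations = 500,
                        n_haplotypes = length(panel$parents),
                        n_reps = 200, sparse_min = 10,
                        alignment = NULL, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (generations < 0) stop("generations must be >= 0")
  map <- panel$map
  founders <- panel$alleles
  nf <- nrow(founders)
  chroms <- map_chromosomes(map)
  chrom_idx <- lapply(chroms, function(ch) which(map$markers$chrom == ch))
  names(chrom_idx) <- chroms
  draw <- function() {
    A <- matrix(0L, n_haplotypes, ncol(founders))
    for (ch in chroms) {
      idx <- chrom_idx[[ch]]
      pos <- map$markers$pos[idx]
      lo <- min(pos); len <- max(pos) - lo
      Lc <- len / 100  # Morgans
      for (h in seq_len(n_haplotypes)) {
        nb <- stats::rpois(1, generations * Lc)
        breaks <- sort(stats::runif(nb, 0, len))
        bounds <- c(0, breaks, len + 1e-9)
        block <- findInterval(pos - lo, bounds, rightmost.closed = TRUE)
        src <- sample.int(nf, length(bounds) - 1, replace = TRUE)
        A[h, idx] <- founders[cbind(src[block], idx)]
      }
    }
    A
  }
  .pooled_null(panel, grid, w1, w2, window_cM, na_policy, sparse_min,
               alignment, draw, n_reps, seed,
               sampler = "mosaic", generations = generations)
}

.pooled_null <- function(panel, grid, w1, w2, window_cM, na_policy,
                         sparse_min, alignment, draw, n_reps, seed,
                         sampler, generations = NULL) {
  loci <- transfer_grid(grid$loci, alignment, panel$map)
  wp <- window_plan(panel$map, loci, w1, w2, window_cM, sparse_min)
  live <- which(wp$s_map > 0)
  set.seed(as.integer(seed))
  pooled <- vector("list", n_reps)
  pr <- NULL
  for (r in seq_len(n_reps)) {
    A <- draw()
    if (is.null(pr)) pr <- pair_index(nrow(A))
    out <- matrix(NA_real_, length(live), nrow(pr))
    for (k in seq_along(live)) {
      t <- live[k]
      plan <- wp$plans[[t]]
      s <- .locus_scores(A, plan, pr$i, pr$j, na_policy)
      # identity kinship: extended score reduces to P * s_tilde
      out[k, ] <- wp$P[t] * (s / wp$s_map[t])
    }
    pooled[[r]] <- as.vector(out)
  }
  structure(list(sample = unlist(pooled), sampler = sampler,
                 n_reps = n_reps, generations = generations, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null similarity distribution (%s sampling%s): %d values, %d reps\n",
              x$sampler,
              if (!is.null(x$generations))
                paste0(", ", x$generations, " generations") else "",
              length(x$sample), x$n_reps))
  q <- stats::quantile(x$sample, c(.5, .9, .95, .99), type = 1)
  cat("  quantiles:", paste(sprintf("%s=%.3f", names(q), q), collapse = " "), "\n")
  invisible(x)
}

#' Empirical clustering threshold
#'
#' The `(1 - alpha)` empirical quantile (inverse-CDF order statistic,
#' `quantile(type = 1)`) of a pooled null distribution of similarity
#' scores.  Pairs scoring at or above this value at a locus are accepted
#' as sharing an ancestral allele at type-I error `alpha`.
#'
#' @param null a [equilibrium_null()] / [mosaic_null()] result.
#' @param alpha type I error in (0, 1).
#' @return An object of class `threshold_estimate` with elements `alpha`,
#'   `value`, `sampler`.
#' @export
empirical_threshold <- function(null, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (length(null$sample) == 0) stop("empty null sample")
  v <- unname(stats::quantile(null$sample, 1 - alpha, type = 1))
  structure(list(alpha = alpha, value = v, sampler = null$sampler),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Clustering threshold %.4f (alpha = %g, %s sampling)\n",
              x$value, x$alpha, x$sampler))
  invisible(x)
}
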