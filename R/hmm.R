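#' Classify a pair's similarity series with a hidden Markov model
#'
#' Fits Gaussian-emission HMMs with 2, 3 and 4 hidden states to the
#' similarity series of one haplotype pair by EM (Baum-Welch, 5 random
#' restarts per state count), picks the state count with the smallest
#' BIC, decodes the series by Viterbi, and maps the loci whose decoded
#' state has the highest emission mean to class 1 (the pair shares an
#' ancestral allele there); all other states map to 0.
#'
#' A state count whose best fit contains a degenerate state (variance
#' below 1e-8) is discarded; if every candidate fails to converge an
#' error advises the threshold method.
#'
#' @param series numeric vector of similarity scores over the scan loci
#'   (length >= 10).
#' @param candidate_states integer vector of state counts (default 2:4).
#' @param seed master seed; restart seeds are derived from it.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `pair_hmm`: `series` (0/1 per locus),
#'   `n_states`, `bic` (named per candidate), `fit` (means, variances,
#'   transition matrix), `states` (Viterbi path).
#' @export
hmm_classify <- function(series, candidate_states = 2:4, seed = 1,
                         max_iter = 200, tol = 1e-6) {
  x <- as.numeric(series)
  Tn <- length(x)
  if (Tn < 10) stop("series shorter than 10 loci; use the threshold method")
  if (stats::sd(x) < 1e-10) {
    # constant signal: a single effective state, everything class 1
    return(structure(list(series = rep(1L, Tn), n_states = 1L,
                          bic = c(`1` = NA_real_),
                          fit = list(means = x[1], vars = 0),
                          states = rep(1L, Tn)),
                     class = "pair_hmm"))
  }
  bics <- stats::setNames(rep(NA_real_, length(candidate_states)),
                          candidate_states)
  fits <- vector("list", length(candidate_states))
  for (ci in seq_along(candidate_states)) {
    ns <- candidate_states[ci]
    best <- NULL
    for (r in 1:5) {
      f <- tryCatch(.hmm_em(x, ns, seed = seed * 131L + ns * 17L + r,
                            max_iter = max_iter, tol = tol),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (is.null(best) || any(best$vars < 1e-8) || !is.finite(best$loglik))
      next
    k <- ns * (ns - 1) + (ns - 1) + 2 * ns  # transitions + initial + emissions
    bics[ci] <- -2 * best$loglik + k * log(Tn)
    fits[[ci]] <- best
  }
  ok <- which(!is.na(bics))
  if (length(ok) == 0)
    stop("EM failed to converge for every candidate state count; ",
         "use the threshold clustering method instead")
  sel <- ok[which.min(bics[ok])]
  fit <- fits[[sel]]
  path <- .hmm_viterbi(x, fit)
  top <- which.max(fit$means)
  structure(list(series = as.integer(path == top),
                 n_states = candidate_states[sel],
                 bic = bics, fit = fit, states = path),
            class = "pair_hmm")
}

#' @export
print.pair_hmm <- function(x, ...) {
  cat(sprintf("Pair HMM: %d states; %d of %d loci in the shared class\n",
              x$n_states, sum(x$series), length(x$series)))
  invisible(x)
}

# Baum-Welch for a univariate Gaussian HMM (scaled forward-backward)
.hmm_em <- function(x, ns, seed, max_iter = 200, tol = 1e-6) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  Tn <- length(x)
  # variance floor: similarity series often contain exactly repeated
  # values (e.g. runs of 1), which would collapse a Gaussian state
  vfloor <- max(1e-8, 1e-4 * stats::var(x))
  qs <- stats::quantile(x, probs = seq(0.1, 0.9, length.out = ns), type = 1)
  mu <- as.numeric(qs) + stats::rnorm(ns, 0, stats::sd(x) / 10)
  v <- rep(stats::var(x) / ns, ns)
  A <- matrix(0.1 / (ns - 1), ns, ns); diag(A) <- 0.9
  pi0 <- rep(1 / ns, ns)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    B <- vapply(seq_len(ns), function(s)
      stats::dnorm(x, mu[s], sqrt(pmax(v[s], 1e-12))), numeric(Tn))
    B <- pmax(B, 1e-300)
    # forward
    al <- matrix(0, Tn, ns); sc <- numeric(Tn)
    al[1, ] <- pi0 * B[1, ]; sc[1] <- sum(al[1, ]); al[1, ] <- al[1, ] / sc[1]
    for (t in 2:Tn) {
      al[t, ] <- (al[t - 1, ] %*% A) * B[t, ]
      sc[t] <- sum(al[t, ]); al[t, ] <- al[t, ] / sc[t]
    }
    ll <- sum(log(sc))
    # backward
    be <- matrix(0, Tn, ns); be[Tn, ] <- 1
    for (t in (Tn - 1):1)
      be[t, ] <- (A %*% (B[t + 1, ] * be[t + 1, ])) / sc[t + 1]
    g <- al * be
    g <- g / rowSums(g)
    # transition expectations
    xi <- matrix(0, ns, ns)
    for (t in 1:(Tn - 1)) {
      m <- (al[t, ] %o% (B[t + 1, ] * be[t + 1, ])) * A
      xi <- xi + m / sum(m)
    }
    pi0 <- g[1, ]
    A <- xi / pmax(rowSums(xi), 1e-300)
    w <- colSums(g)
    mu <- colSums(g * x) / w
    v <- colSums(g * (outer(x, mu, "-")^2)) / w
    v <- pmax(v, vfloor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(means = mu, vars = v, trans = A, init = pi0, loglik = ll)
}

.hmm_viterbi <- function(x, fit) {
  ns <- length(fit$means)
  Tn <- length(x)
  logB <- vapply(seq_len(ns), function(s)
    stats::dnorm(x, fit$means[s], sqrt(pmax(fit$vars[s], 1e-12)), log = TRUE),
    numeric(Tn))
  logA <- log(pmax(fit$trans, 1e-300))
  d <- matrix(-Inf, Tn, ns); psi <- matrix(0L, Tn, ns)
  d[1, ] <- log(pmax(fit$init, 1e-300)) + logB[1, ]
  for (t in 2:Tn) for (s in seq_len(ns)) {
    cand <- d[t - 1, ] + logA[, s]
    psi[t, s] <- which.max(cand)
    d[t, s] <- cand[psi[t, s]] + logB[t, s]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(d[Tn, ])
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
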