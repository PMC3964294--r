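#' Regression blocks for one scan locus
#'
#' Builds the locus term of the connected marker-regression model: for
#' each individual, the expected allele dosage of each parent (connected
#' model) or of each ancestral-allele class (LD model, dosages of member
#' parents summed), derived from the parental-origin genotype
#' probabilities.  Because class dosages sum to 2 for every individual,
#' the block is returned under a sum-to-zero contrast over classes
#' (`n_classes - 1` columns when full-rank).
#'
#' @param probs a [genotype_probabilities()] result.
#' @param t locus row index in `probs$loci`.
#' @param clustering optional [local_clustering()] on the same loci; when
#'   `NULL` each parent is its own class (connected model).
#' @return list with `X` (n x (C-1) contrast-coded dosage matrix, rows in
#'   stacked family order), `dosage` (n x C raw class dosages), `classes`
#'   (class labels), `n_classes`.
#' @export
design_matrix <- function(probs, t, clustering = NULL) {
  design <- probs$design
  cls <- locus_classes(design, clustering, t)
  C <- cls$n_classes
  n <- sum(design$n)
  D <- matrix(0, n, C)
  off <- 0L
  for (k in seq_len(nrow(design$families))) {
    id <- design$families$id[k]
    P <- probs$fam[[id]][, t, , drop = FALSE]
    ni <- dim(P)[1]
    di <- 2 * P[, 1, 1] + P[, 1, 2]       # dosage of parent_i's allele
    dj <- P[, 1, 2] + 2 * P[, 1, 3]       # dosage of parent_j's allele
    ci <- cls$class_of[[design$families$parent_i[k]]]
    cj <- cls$class_of[[design$families$parent_j[k]]]
    rows <- off + seq_len(ni)
    D[rows, ci] <- D[rows, ci] + di
    D[rows, cj] <- D[rows, cj] + dj
    off <- off + ni
  }
  X <- if (C >= 2) D %*% stats::contr.sum(C) else matrix(0, n, 0)
  list(X = X, dosage = D, classes = cls$labels, n_classes = C)
}

# class assignment of each parent at locus t
locus_classes <- function(design, clustering, t) {
  if (is.null(clustering)) {
    labels <- design$parents
    class_of <- as.list(seq_along(labels))
    names(class_of) <- labels
    return(list(class_of = class_of, labels = labels,
                n_classes = length(labels)))
  }
  miss <- setdiff(design$parents, clustering$parents)
  if (length(miss) > 0)
    stop("clustering is missing parent(s): ", paste(miss, collapse = ", "))
  z <- clustering$assign[t, ]
  labels <- sort(unique(z))
  class_of <- as.list(match(z, labels))
  names(class_of) <- clustering$parents
  list(class_of = class_of, labels = paste0("class", labels),
       n_classes = length(labels))
}

family_dummies <- function(design) {
  f <- factor(design$fam_of, levels = design$families$id)
  stats::model.matrix(~ 0 + f)
}

#' Incremental F test of a locus term
#'
#' Ordinary least squares for the null model (family means plus
#' cofactors) and the full model (plus the locus term); the locus term is
#' tested by the incremental sum-of-squares F statistic with `df1` equal
#' to the actual rank gain (reduced when the term is rank-deficient) and
#' `df2` the full-model residual degrees of freedom.  A locus with a
#' single ancestral-allele class contributes no term: the test is skipped
#' and `-log10(p) = 0`.
#'
#' @param y numeric phenotype vector (stacked family order).
#' @param X0 null-model design matrix.
#' @param X1 columns added by the locus term (may have zero columns).
#' @return list with `F`, `df1`, `df2`, `p`, `neglog10p`, `rss0`, `rss1`,
#'   `coef` (full-model coefficients, NA for aliased columns).
#' @export
fit_and_test <- function(y, X0, X1) {
  n <- length(y)
  q0 <- qr(X0)
  rss0 <- sum(qr.resid(q0, y)^2)
  if (is.null(X1) || ncol(X1) == 0) {
    return(list(F = NA_real_, df1 = 0L, df2 = n - q0$rank, p = 1,
                neglog10p = 0, rss0 = rss0, rss1 = rss0, coef = NULL))
  }
  Xf <- cbind(X0, X1)
  q1 <- qr(Xf)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  rss1 <- sum(qr.resid(q1, y)^2)
  if (df1 < 1 || df2 < 1)
    return(list(F = NA_real_, df1 = as.integer(max(df1, 0)), df2 = df2,
                p = 1, neglog10p = 0, rss0 = rss0, rss1 = rss1, coef = NULL))
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  cf <- qr.coef(q1, y)
  list(F = Fstat, df1 = as.integer(df1), df2 = as.integer(df2), p = p,
       neglog10p = -log10(max(p, .Machine$double.xmin)),
       rss0 = rss0, rss1 = rss1, coef = cf)
}

# per-locus dosage blocks; computed once and reused across scans,
# permutations and detection rounds (they do not depend on phenotypes or
# cofactors)
locus_blocks <- function(probs, clustering = NULL) {
  lapply(seq_len(nrow(probs$loci)), function(t)
    design_matrix(probs, t, clustering))
}

# cofactor indices whose locus is within the exclusion half-window of t
.excluded_cofactors <- function(loci, cof_idx, t, exclusion_cM) {
  if (length(cof_idx) == 0) return(integer(0))
  same <- loci$chrom[cof_idx] == loci$chrom[t]
  close <- abs(loci$pos[cof_idx] - loci$pos[t]) <= exclusion_cM / 2 + 1e-9
  cof_idx[same & close]
}

#' Genome scan of the connected or LD QTL model
#'
#' Fits the marker-regression model at every scan locus and tests the
#' locus term against the null model of family means plus cofactors,
#' comparing positions by `-log10(p)` of the incremental F test (the
#' degrees of freedom change from locus to locus in the LD model, so F
#' statistics are not comparable across positions).  Cofactor loci lying
#' within half the exclusion window of the tested position are dropped
#' from both models at that position.
#'
#' @param y phenotype vector in stacked family order.
#' @param probs a [genotype_probabilities()] result.
#' @param clustering optional [local_clustering()] aligned with
#'   `probs$loci`; `NULL` fits the connected (per-parent) model.
#' @param cofactors integer vector of cofactor locus indices (rows of
#'   `probs$loci`).
#' @param exclusion_cM total width of the cofactor exclusion window
#'   (default 10, i.e. 5 cM on each side).
#' @param blocks optional precomputed per-locus dosage blocks (internal
#'   reuse across scans; computed from `probs` and `clustering` when
#'   `NULL`).
#' @return An object of class `qtl_scan`: a data frame with columns
#'   `chrom`, `pos`, `F`, `df1`, `df2`, `p`, `neglog10p`, `n_classes`.
#' @export
qtl_scan <- function(y, probs, clustering = NULL, cofactors = integer(0),
                     exclusion_cM = 10, blocks = NULL) {
  loci <- probs$loci
  if (!is.null(clustering) && nrow(clustering$loci) != nrow(loci))
    stop("clustering and genotype probabilities cover different loci")
  if (is.null(blocks)) blocks <- locus_blocks(probs, clustering)
  Ffam <- family_dummies(probs$design)
  cof_blocks <- lapply(cofactors, function(ci) blocks[[ci]]$X)
  nt <- nrow(loci)
  res <- data.frame(chrom = loci$chrom, pos = loci$pos,
                    F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                    p = NA_real_, neglog10p = NA_real_,
                    n_classes = NA_integer_, stringsAsFactors = FALSE)
  for (t in seq_len(nt)) {
    drop <- .excluded_cofactors(loci, cofactors, t, exclusion_cM)
    use <- which(!(cofactors %in% drop))
    X0 <- do.call(cbind, c(list(Ffam), cof_blocks[use]))
    blk <- blocks[[t]]
    ft <- fit_and_test(y, X0, blk$X)
    res$F[t] <- ft$F; res$df1[t] <- ft$df1; res$df2[t] <- ft$df2
    res$p[t] <- ft$p; res$neglog10p[t] <- ft$neglog10p
    res$n_classes[t] <- blk$n_classes
  }
  attr(res, "cofactors") <- cofactors
  attr(res, "model") <- if (is.null(clustering)) "connected" else "ld"
  class(res) <- c("qtl_scan", "data.frame")
  res
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("QTL scan (%s model): %d loci", attr(x, "model"), nrow(x)))
  if (length(attr(x, "cofactors")) > 0)
    cat(",", length(attr(x, "cofactors")), "cofactor(s)")
  cat("\n")
  t <- which.max(x$neglog10p)
  cat(sprintf("  max -log10(p) = %.3f at %s:%.1f cM (F = %.2f, df = %d/%d)\n",
              x$neglog10p[t], x$chrom[t], x$pos[t], x$F[t], x$df1[t],
              x$df2[t]))
  invisible(x)
}

#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  graphics::plot(x$pos, x$neglog10p, type = "l", xlab = "position (cM)",
                 ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold)) {
    if (inherits(threshold, "threshold_estimate")) threshold <- threshold$value
    graphics::abline(h = threshold, lty = 2)
  }
  invisible(x)
}

#' Genome-wide permutation threshold
#'
#' Doerge-Churchill permutation threshold on the `-log10(p)` scale:
#' phenotypes are permuted within family (preserving the family-mean
#' structure), the genome-wide maximum `-log10(p)` of the cofactor-free
#' scan is recorded for each permutation, and the threshold is the
#' empirical `(1 - alpha)` quantile of these maxima.
#'
#' @inheritParams qtl_scan
#' @param n_perm number of permutations.
#' @param alpha genome-wide type I error (default 0.10).
#' @param seed integer seed.
#' @return list with `threshold`, `alpha`, `n_perm`, `maxima`.
#' @export
permutation_threshold <- function(y, probs, clustering = NULL,
                                  n_perm = 1000, alpha = 0.10, seed = 1,
                                  blocks = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  design <- probs$design
  n <- length(y)
  fam <- factor(design$fam_of, levels = design$families$id)
  Yp <- matrix(0, n, n_perm)
  idx <- split(seq_len(n), fam)
  for (b in seq_len(n_perm)) {
    yp <- y
    for (ii in idx) yp[ii] <- y[sample(ii)]
    Yp[, b] <- yp
  }
  maxima <- .scan_maxima(Yp, probs, clustering, blocks)
  list(threshold = unname(stats::quantile(maxima, 1 - alpha, type = 1)),
       alpha = alpha, n_perm = n_perm, maxima = maxima)
}

# genome-wide max -log10(p) of the cofactor-free scan for each column of
# the phenotype matrix Y (shared per-locus projections, BLAS-heavy path)
.scan_maxima <- function(Y, probs, clustering = NULL, blocks = NULL) {
  design <- probs$design
  if (is.null(blocks)) blocks <- locus_blocks(probs, clustering)
  n <- nrow(Y)
  Ffam <- family_dummies(design)
  q0 <- qr(Ffam)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  tot <- colSums(Y^2)
  rss0 <- tot - colSums(crossprod(Q0, Y)^2)
  nt <- nrow(probs$loci)
  best <- rep(0, ncol(Y))
  for (t in seq_len(nt)) {
    blk <- blocks[[t]]
    if (ncol(blk$X) == 0) next
    q1 <- qr(cbind(Ffam, blk$X))
    df1 <- q1$rank - q0$rank
    df2 <- n - q1$rank
    if (df1 < 1 || df2 < 1) next
    Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
    rss1 <- tot - colSums(crossprod(Q1, Y)^2)
    Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
    lp <- -stats::pf(Fst, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
    best <- pmax(best, lp)
  }
  best
}

#' Iterative cofactor QTL detection
#'
#' A forward-selection approximation of iterative cofactor mapping:
#' scan with the current cofactors, add the genome-wide maximum as a new
#' cofactor while it exceeds the threshold (positions within half the
#' exclusion window of a cofactor are ineligible), then refine each
#' cofactor's position by rescanning with the others held fixed, and
#' iterate to a fixed point (at most `max_rounds` rounds).  The final
#' cofactors are reported as QTL together with the joint model fit.
#'
#' @inheritParams qtl_scan
#' @param threshold detection threshold on the `-log10(p)` scale (a
#'   number or the result of [permutation_threshold()]).
#' @param max_rounds iteration cap; non-convergence returns the last
#'   state with a warning.
#' @return An object of class `qtl_model`: `qtl` (data frame of detected
#'   loci), `fit` (joint-model estimates), `scan` (final scan), plus the
#'   call configuration.
#' @export
detect_qtl <- function(y, probs, clustering = NULL, threshold,
                       exclusion_cM = 10, max_rounds = 20, blocks = NULL) {
  if (is.list(threshold)) threshold <- threshold$threshold
  loci <- probs$loci
  if (is.null(blocks)) blocks <- locus_blocks(probs, clustering)
  cof <- integer(0)
  converged <- FALSE
  final_scan <- NULL
  for (round in seq_len(max_rounds)) {
    sc <- qtl_scan(y, probs, clustering, cof, exclusion_cM, blocks = blocks)
    final_scan <- sc
    elig <- rep(TRUE, nrow(loci))
    for (ci in cof) {
      near <- loci$chrom == loci$chrom[ci] &
        abs(loci$pos - loci$pos[ci]) <= exclusion_cM / 2 + 1e-9
      elig[near] <- FALSE
    }
    lp <- ifelse(elig, sc$neglog10p, -Inf)
    t_new <- which.max(lp)
    if (lp[t_new] > threshold) {
      cof <- c(cof, t_new)
      next
    }
    # refinement: reposition each cofactor with the others fixed
    moved <- FALSE
    if (length(cof) > 0) for (k in seq_along(cof)) {
      others <- cof[-k]
      sck <- qtl_scan(y, probs, clustering, others, exclusion_cM,
                      blocks = blocks)
      elig <- rep(TRUE, nrow(loci))
      for (ci in others) {
        near <- loci$chrom == loci$chrom[ci] &
          abs(loci$pos - loci$pos[ci]) <= exclusion_cM / 2 + 1e-9
        elig[near] <- FALSE
      }
      lpk <- ifelse(elig, sck$neglog10p, -Inf)
      t_best <- which.max(lpk)
      if (lpk[t_best] > threshold && t_best != cof[k]) {
        if (abs(loci$pos[t_best] - loci$pos[cof[k]]) > 1e-9 ||
            loci$chrom[t_best] != loci$chrom[cof[k]]) moved <- TRUE
        cof[k] <- t_best
      } else if (lpk[t_best] <= threshold) {
        # cofactor no longer supported: drop it
        cof <- cof[-k]
        moved <- TRUE
        break
      }
    }
    if (!moved) { converged <- TRUE; break }
  }
  if (!converged && length(cof) > 0)
    warning("QTL detection did not reach a fixed point in ", max_rounds,
            " rounds; returning the last state")
  fit <- .joint_fit(y, probs, clustering, cof, blocks)
  qtl <- if (length(cof) > 0)
    data.frame(chrom = loci$chrom[cof], pos = loci$pos[cof],
               locus = cof, stringsAsFactors = FALSE)
  else
    data.frame(chrom = character(0), pos = numeric(0), locus = integer(0))
  structure(list(qtl = qtl, fit = fit, scan = final_scan,
                 threshold = threshold, exclusion_cM = exclusion_cM,
                 model = if (is.null(clustering)) "connected" else "ld",
                 converged = converged),
            class = "qtl_model")
}

# joint OLS fit of family means + all detected QTL terms
.joint_fit <- function(y, probs, clustering, cof, blocks = NULL) {
  design <- probs$design
  Ffam <- family_dummies(design)
  blocks <- if (is.null(blocks)) lapply(cof, function(ci)
    design_matrix(probs, ci, clustering)) else blocks[cof]
  X <- do.call(cbind, c(list(Ffam), lapply(blocks, `[[`, "X")))
  q <- qr(X)
  cf <- qr.coef(q, y)
  res <- qr.resid(q, y)
  df <- length(y) - q$rank
  mu <- cf[seq_len(ncol(Ffam))]
  names(mu) <- design$families$id
  effects <- list()
  off <- ncol(Ffam)
  for (b in seq_along(blocks)) {
    C <- blocks[[b]]$n_classes
    beta <- cf[off + seq_len(C - 1)]
    beta[is.na(beta)] <- 0
    a <- as.vector(stats::contr.sum(C) %*% beta)  # sum-to-zero effects
    names(a) <- blocks[[b]]$classes
    effects[[b]] <- a
    off <- off + (C - 1)
  }
  list(family_means = mu, effects = effects,
       sigma2 = sum(res^2) / max(df, 1), df_residual = df)
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("QTL model (%s): %d QTL detected (threshold %.3f)\n",
              x$model, nrow(x$qtl), x$threshold))
  if (nrow(x$qtl) > 0)
    for (k in seq_len(nrow(x$qtl)))
      cat(sprintf("  QTL %d at %s:%.1f cM\n", k, x$qtl$chrom[k],
                  x$qtl$pos[k]))
  cat(sprintf("  residual variance %.4f\n", x$fit$sigma2))
  invisible(x)
}

#' @export
coef.qtl_model <- function(object, ...) {
  c(object$fit$family_means,
    unlist(lapply(seq_along(object$fit$effects), function(b)
      stats::setNames(object$fit$effects[[b]],
                      paste0("qtl", b, ".",
                             names(object$fit$effects[[b]]))))))
}

#' @export
summary.qtl_model <- function(object, ...) {
  object
}
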