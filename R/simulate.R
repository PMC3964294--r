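#' Simulate a parent panel descending from a few ancestors
#'
#' Ancestors carry independent equifrequent biallelic markers (alleles 1
#' and 2) on a regular dense map.  Each parent line is a mosaic of the
#' ancestors: per chromosome the number of crossover breaks is
#' `Poisson(generations * L_c)` (`L_c` length in Morgans), break
#' positions are uniform, and each inter-break block copies one
#' uniformly drawn ancestor.  The ancestor-of-origin of every marker is
#' returned as a truth track for recovery studies.
#'
#' @param n_ancestors number of founder ancestors (default 3).
#' @param n_parents number of parent lines (default 12).
#' @param chr_length_cM chromosome length(s) in cM; one chromosome of
#'   150 cM by default.
#' @param marker_step_cM marker spacing (default 1 cM).
#' @param generations mosaic generations; 0 makes every parent an exact
#'   ancestor copy (default 5, giving ancestral blocks long relative to a
#'   20 cM window, as in highly related breeding panels).
#' @param seed integer seed.
#' @return list with `panel` (a [haplotype_panel()]), `truth` (parents x
#'   markers matrix of ancestor indices), `ancestors` (allele matrix).
#' @export
simulate_parent_panel <- function(n_ancestors = 3, n_parents = 12,
                                  chr_length_cM = 150, marker_step_cM = 1,
                                  generations = 5, seed = 1) {
  stopifnot(n_ancestors >= 1, n_parents >= n_ancestors | n_parents >= 1,
            marker_step_cM > 0, generations >= 0)
  set.seed(as.integer(seed))
  maps <- lapply(seq_along(chr_length_cM), function(c) {
    pos <- seq(0, chr_length_cM[c], by = marker_step_cM)
    data.frame(chrom = paste0("chr", c),
               marker = sprintf("c%d_m%03d", c, seq_along(pos)),
               pos = pos, stringsAsFactors = FALSE)
  })
  map <- genetic_map(do.call(rbind, maps))
  M <- n_markers(map)
  anc <- matrix(sample(1:2, n_ancestors * M, replace = TRUE),
                n_ancestors, M)
  A <- matrix(0L, n_parents, M)
  truth <- matrix(0L, n_parents, M)
  for (c in seq_along(chr_length_cM)) {
    idx <- which(map$markers$chrom == paste0("chr", c))
    pos <- map$markers$pos[idx]
    len <- chr_length_cM[c]
    for (h in seq_len(n_parents)) {
      nb <- stats::rpois(1, generations * len / 100)
      bounds <- c(0, sort(stats::runif(nb, 0, len)), len + 1e-9)
      block <- findInterval(pos, bounds, rightmost.closed = TRUE)
      src <- sample.int(n_ancestors, length(bounds) - 1, replace = TRUE)
      A[h, idx] <- anc[cbind(src[block], idx)]
      truth[h, idx] <- src[block]
    }
  }
  rownames(A) <- sprintf("P%02d", seq_len(n_parents))
  rownames(truth) <- rownames(A)
  colnames(truth) <- map$markers$marker
  list(panel = haplotype_panel(A, map), truth = truth, ancestors = anc)
}

#' Thin a dense map into a consensus map
#'
#' Keeps, per chromosome, the marker nearest to each rung of a
#' `step_cM`-spaced ladder (terminal markers always kept).  The retained
#' markers keep their names, so the thinned map shares anchors with the
#' dense map everywhere.
#'
#' @param map a [genetic_map()].
#' @param step_cM target spacing (default 5 cM).
#' @return A [genetic_map()].
#' @export
thin_map <- function(map, step_cM = 5) {
  m <- map$markers
  keep <- unlist(lapply(unique(m$chrom), function(ch) {
    i <- which(m$chrom == ch)
    targets <- seq(min(m$pos[i]), max(m$pos[i]), by = step_cM)
    targets <- unique(c(targets, max(m$pos[i])))
    unique(i[vapply(targets, function(tt) which.min(abs(m$pos[i] - tt)),
                    integer(1))])
  }))
  genetic_map(m[sort(keep), ])
}

#' Lay out a connected multi-cross design
#'
#' Pairs the parents into `n_families` biparental crosses: first
#' consecutive disjoint pairs covering all parents, then bridging pairs
#' that connect neighbouring crosses, giving a connected design in which
#' some parents found several families.
#'
#' @param panel a [haplotype_panel()].
#' @param n_families number of families (default 8).
#' @param family_size individuals per family (default 60).
#' @param type family type for all crosses (default `"F2"`).
#' @return data frame of families suitable for [cross_design()], with an
#'   `n` column.
#' @export
design_families <- function(panel, n_families = 8, family_size = 60,
                            type = "F2") {
  p <- panel$parents
  np <- length(p)
  pairs <- list()
  k <- 1
  while (2 * k <= np && length(pairs) < n_families) {
    pairs[[length(pairs) + 1]] <- c(p[2 * k - 1], p[2 * k])
    k <- k + 1
  }
  b <- 2
  while (length(pairs) < n_families) {
    pairs[[length(pairs) + 1]] <- c(p[(b - 1) %% np + 1], p[b %% np + 1])
    b <- b + 2
  }
  data.frame(id = sprintf("F%02d", seq_len(n_families)),
             parent_i = vapply(pairs, `[`, "", 1),
             parent_j = vapply(pairs, `[`, "", 2),
             type = type, n = family_size, stringsAsFactors = FALSE)
}

#' Assign QTL alleles from the local clustering
#'
#' The parents of the biggest ancestral-allele class at the QTL locus
#' receive the mutated allele; all others the wild type.  Ties between
#' biggest classes are broken by a uniform draw.
#'
#' @param clustering a [local_clustering()].
#' @param t locus row index of the QTL in `clustering$loci`.
#' @param seed optional seed for the tie-break draw.
#' @return named logical vector: `TRUE` for mutant parents.
#' @export
assign_qtl_alleles <- function(clustering, t, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- clustering$assign[t, ]
  sizes <- table(z)
  big <- names(sizes)[sizes == max(sizes)]
  pick <- if (length(big) > 1) sample(big, 1) else big
  out <- z == as.integer(pick)
  names(out) <- clustering$parents
  out
}

#' Simulate descendant genotypes and phenotypes
#'
#' Descendant genomes are simulated by the meiosis chain of each family
#' type (the same Haldane transition kernels the analysis uses) jointly
#' at the consensus markers and at the QTL position, so the QTL genotype
#' is an exact draw from its conditional distribution given the marker
#' genotypes.  The phenotype is `N(0, 1)` noise plus `effect` times the
#' number of mutated alleles carried.  Markers at which the two family
#' parents are alike in state carry no parental-origin information in a
#' real cross; they are masked to `NA` when `mask_uninformative` is set.
#'
#' @param fam_table a [design_families()]-style data frame (`id`,
#'   `parent_i`, `parent_j`, `type`, `n`).
#' @param panel the parent [haplotype_panel()].
#' @param consensus_map consensus [genetic_map()] (markers must be a
#'   subset, by name, of the panel map when masking is on).
#' @param qtl list with `chrom`, `pos` (consensus cM), `effect`, and
#'   `mutant` — a named logical over parents ([assign_qtl_alleles()]);
#'   `NULL` simulates the no-QTL null.
#' @param mask_uninformative mask origin codes at markers that do not
#'   segregate within the family (default `TRUE`).
#' @param seed integer seed.
#' @return list with `design` (a [cross_design()]) and `pheno` (numeric,
#'   stacked family order).
#' @export
simulate_family_data <- function(fam_table, panel, consensus_map,
                                 qtl = NULL, mask_uninformative = TRUE,
                                 seed = 1) {
  set.seed(as.integer(seed))
  cm <- consensus_map$markers
  genos <- list()
  pheno <- numeric(0)
  for (k in seq_len(nrow(fam_table))) {
    type <- fam_table$type[k]
    ni <- fam_table$n[k]
    G <- matrix(NA_integer_, ni, nrow(cm))
    qg <- integer(ni)
    for (ch in unique(cm$chrom)) {
      sel <- which(cm$chrom == ch)
      pos <- cm$pos[sel]
      qhere <- !is.null(qtl) && qtl$chrom == ch
      simpos <- if (qhere) sort(unique(c(pos, qtl$pos))) else pos
      sim <- .simulate_origin(ni, simpos, type)
      G[, sel] <- sim[, match(pos, simpos), drop = FALSE]
      if (qhere) qg <- sim[, match(qtl$pos, simpos)]
    }
    if (!is.null(qtl)) {
      mi <- qtl$mutant[[fam_table$parent_i[k]]]
      mj <- qtl$mutant[[fam_table$parent_j[k]]]
      copies <- (2 - qg) * mi + qg * mj
      y <- stats::rnorm(ni) + qtl$effect * copies
    } else {
      y <- stats::rnorm(ni)
    }
    if (mask_uninformative) {
      ai <- panel$alleles[fam_table$parent_i[k],
                          match(cm$marker, colnames(panel$alleles))]
      aj <- panel$alleles[fam_table$parent_j[k],
                          match(cm$marker, colnames(panel$alleles))]
      uninf <- is.na(ai) | is.na(aj) | ai == aj
      G[, uninf] <- NA_integer_
    }
    genos[[fam_table$id[k]]] <- G
    pheno <- c(pheno, y)
  }
  design <- cross_design(fam_table[, c("id", "parent_i", "parent_j", "type")],
                         genos, consensus_map, panel$parents)
  list(design = design, pheno = pheno)
}

# simulate parental-origin codes (0/1/2 copies of parent_j's allele) for
# n individuals at the given positions, per family type
.simulate_origin <- function(n, pos, type) {
  L <- length(pos)
  r <- haldane_r(diff(pos))
  gamete <- function() {
    # one meiotic product of the F1: 0/1 chain with switch prob r
    g <- matrix(0L, n, L)
    g[, 1] <- sample(0:1, n, replace = TRUE)
    for (t in seq_len(L - 1)) {
      sw <- stats::runif(n) < r[t]
      g[, t + 1] <- ifelse(sw, 1L - g[, t], g[, t])
    }
    g
  }
  meiosis_from <- function(h1, h2) {
    # gamete of an individual with homologs h1, h2 (0/1 matrices)
    use2 <- matrix(0L, n, L)
    use2[, 1] <- sample(0:1, n, replace = TRUE)
    for (t in seq_len(L - 1)) {
      sw <- stats::runif(n) < r[t]
      use2[, t + 1] <- ifelse(sw, 1L - use2[, t], use2[, t])
    }
    ifelse(use2 == 1L, h2, h1)
  }
  switch(type,
    F2 = gamete() + gamete(),
    F3 = {
      h1 <- gamete(); h2 <- gamete()      # the F2 individual's homologs
      meiosis_from(h1, h2) + meiosis_from(h1, h2)
    },
    BC = gamete(),                         # second gamete is parent_i
    RIL = {
      rr <- 2 * r / (1 + 2 * r)
      g <- matrix(0L, n, L)
      g[, 1] <- sample(0:1, n, replace = TRUE)
      for (t in seq_len(L - 1)) {
        sw <- stats::runif(n) < rr[t]
        g[, t + 1] <- ifelse(sw, 1L - g[, t], g[, t])
      }
      2L * g
    })
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/factor vectors of class labels over the same items.
#' @return the Hubert-Arabie adjusted Rand index (1 = identical
#'   partitions, 0 = chance agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  N <- comb2(sum(tab))
  expected <- si * sj / N
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Power and precision of QTL detection
#'
#' For each method, power is the fraction of replicates with at least
#' one detected QTL (averaged over simulated positions) and precision at
#' interval `w` is the fraction of detecting replicates in which a
#' detected QTL lies within `w` cM of the simulated QTL (replicates with
#' no detection are excluded).  A one-sided paired t-test across the
#' simulated positions tests the superiority of the second method.
#'
#' @param detections named list of two methods; each is a list over
#'   simulated positions, each a list over replicates of numeric vectors
#'   of detected positions (cM, single chromosome).
#' @param truth numeric vector of simulated QTL positions (one per
#'   position entry).
#' @param intervals surrounding intervals in cM (default `c(1, 2, 5, 10)`).
#' @return An object of class `precision_report`: `precision` (% per
#'   method x interval), `power` (% per method), `per_position` tables,
#'   and `p_value` — one-sided paired t-test p values (second method
#'   minus first) for each interval and for power.
#' @export
evaluate_detections <- function(detections, truth,
                                intervals = c(1, 2, 5, 10)) {
  stopifnot(length(detections) == 2)
  methods <- names(detections)
  npos <- length(truth)
  prec <- lapply(detections, function(det) {
    m <- matrix(NA_real_, npos, length(intervals),
                dimnames = list(NULL, paste0(intervals, "cM")))
    for (q in seq_len(npos)) {
      hits <- det[[q]]
      got <- lengths(hits) > 0
      if (!any(got)) next
      for (w in seq_along(intervals))
        m[q, w] <- 100 * mean(vapply(hits[got], function(d)
          any(abs(d - truth[q]) <= intervals[w] + 1e-9), logical(1)))
    }
    m
  })
  pow <- lapply(detections, function(det)
    vapply(det, function(hits) 100 * mean(lengths(hits) > 0), numeric(1)))
  pvals <- c(vapply(seq_along(intervals), function(w) {
    d <- prec[[2]][, w] - prec[[1]][, w]
    if (sum(!is.na(d)) < 2 || stats::sd(d, na.rm = TRUE) == 0) NA_real_
    else stats::t.test(prec[[2]][, w], prec[[1]][, w], paired = TRUE,
                       alternative = "greater")$p.value
  }, numeric(1)),
  power = if (length(pow[[1]]) < 2 ||
              isTRUE(stats::sd(pow[[2]] - pow[[1]]) == 0)) NA_real_
          else stats::t.test(pow[[2]], pow[[1]], paired = TRUE,
                             alternative = "greater")$p.value)
  names(pvals) <- c(paste0(intervals, "cM"), "power")
  structure(list(
    precision = do.call(rbind, lapply(prec, colMeans, na.rm = TRUE)),
    power = vapply(pow, mean, numeric(1)),
    per_position = list(precision = prec, power = pow),
    p_value = pvals, methods = methods, intervals = intervals),
    class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Power and mapping precision (%)\n")
  tab <- cbind(x$precision, power = x$power)
  print(round(tab, 2))
  cat("one-sided paired t-test,", x$methods[2], ">", x$methods[1], ":\n")
  print(signif(x$p_value, 3))
  invisible(x)
}
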