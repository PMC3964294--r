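#' Multipoint parental-origin genotype probabilities
#'
#' For every individual of every family, computes the probability of each
#' parental-origin genotype (`ii`, `ij`, `jj`) at each scan locus given
#' all marker observations of the chromosome, by hidden-Markov
#' forward-backward over the ordered union of marker and scan positions.
#'
#' Transition kernels use the Haldane map function
#' `r(d) = (1 - exp(-2 d / 100)) / 2`:
#' * F2: two independent gametes, the classical 3-state kernel;
#' * BC: two states (`ii`, `ij`) with transition `r`;
#' * RIL: two absorbing homozygote states with `r_RIL = 2 r / (1 + 2 r)`;
#' * F3: hidden F2 chain with one selfing-generation genotype update
#'   applied at each locus, both to interpret the observed F3 marker
#'   genotypes and to report F3 probabilities (a one-generation
#'   approximation of the full two-generation multipoint chain).
#'
#' Probabilities are reported over the three ordered classes; classes a
#' family type cannot reach (e.g. `jj` in a BC) carry probability 0.
#'
#' @param design a [cross_design()].
#' @param grid a [build_scan_grid()] on the consensus map.
#' @return An object of class `genotype_probs`: `loci` (= `grid$loci`),
#'   `fam` — a named list of `n_ind x n_loci x 3` arrays — and `design`.
#' @export
genotype_probabilities <- function(design, grid) {
  loci <- grid$loci
  out <- vector("list", nrow(design$families))
  names(out) <- design$families$id
  for (k in seq_len(nrow(design$families))) {
    id <- design$families$id[k]
    type <- design$families$type[k]
    G <- design$genotypes[[id]]
    if (any(rowSums(!is.na(G)) == 0))
      warning("family ", id, ": individual(s) with no observed marker; ",
              "probabilities equal the chain prior")
    P <- array(0, c(nrow(G), nrow(loci), 3L))
    for (ch in unique(loci$chrom)) {
      gsel <- which(loci$chrom == ch)
      msel <- which(design$map$markers$chrom == ch)
      if (length(msel) == 0) { P[, gsel, ] <- rep(chain_prior(type), each = nrow(G)); next }
      P[, gsel, ] <- .fb_family(G[, msel, drop = FALSE],
                                design$map$markers$pos[msel],
                                loci$pos[gsel], type)
    }
    out[[id]] <- P
  }
  structure(list(loci = loci, fam = out, design = design),
            class = "genotype_probs")
}

#' @export
print.genotype_probs <- function(x, ...) {
  cat("Genotype probabilities:", length(x$fam), "families x",
      nrow(x$loci), "loci\n")
  invisible(x)
}

haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# one-generation selfing kernel: rows = F2 genotype, cols = F3 genotype
.selfing_kernel <- matrix(c(1, 0,  0,
                            0.25, 0.5, 0.25,
                            0, 0,  1), 3, 3, byrow = TRUE)

chain_prior <- function(type) {
  switch(type,
         F2 = c(0.25, 0.5, 0.25),
         F3 = c(0.375, 0.25, 0.375),
         BC = c(0.5, 0.5, 0),
         RIL = c(0.5, 0, 0.5))
}

# hidden-state machinery per family type
.chain_spec <- function(type) {
  switch(type,
    F2 = list(init = c(.25, .5, .25), cols = 1:3, emit = diag(3),
              trans = function(r) {
                rb <- 1 - r
                matrix(c(rb^2, 2 * r * rb, r^2,
                         r * rb, rb^2 + r^2, r * rb,
                         r^2, 2 * r * rb, rb^2), 3, 3, byrow = TRUE)
              },
              report = diag(3)),
    F3 = list(init = c(.25, .5, .25), cols = 1:3, emit = .selfing_kernel,
              trans = function(r) {
                rb <- 1 - r
                matrix(c(rb^2, 2 * r * rb, r^2,
                         r * rb, rb^2 + r^2, r * rb,
                         r^2, 2 * r * rb, rb^2), 3, 3, byrow = TRUE)
              },
              report = .selfing_kernel),
    BC = list(init = c(.5, .5), cols = 1:2, emit = diag(2),
              trans = function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2,
                                         byrow = TRUE),
              report = diag(2)),
    RIL = list(init = c(.5, .5), cols = c(1, 3), emit = diag(2),
               trans = function(r) {
                 rr <- 2 * r / (1 + 2 * r)
                 matrix(c(1 - rr, rr, rr, 1 - rr), 2, 2, byrow = TRUE)
               },
               report = diag(2)))
}

# forward-backward for one family on one chromosome, vectorized over
# individuals.  G: n x n_markers origin codes; mpos: marker positions;
# qpos: query (scan) positions.  Returns n x length(qpos) x 3.
.fb_family <- function(G, mpos, qpos, type) {
  spec <- .chain_spec(type)
  ns <- length(spec$init)
  n <- nrow(G)
  # ordered union of marker and query positions
  pos <- c(mpos, qpos)
  role <- c(seq_along(mpos), rep(0L, length(qpos)))  # >0: marker column
  qid <- c(rep(0L, length(mpos)), seq_along(qpos))
  o <- order(pos)
  pos <- pos[o]; role <- role[o]; qid <- qid[o]
  # merge coincident positions: a query sitting on a marker
  keep <- rep(TRUE, length(pos))
  for (t in seq_along(pos)[-1]) {
    if (pos[t] - pos[t - 1] < 1e-9) {
      if (role[t] == 0L && role[t - 1] > 0L) {
        qid[t - 1] <- max(qid[t - 1], qid[t]); keep[t] <- FALSE
      } else if (role[t] > 0L && role[t - 1] == 0L) {
        role[t - 1] <- role[t]; qid[t - 1] <- max(qid[t - 1], qid[t])
        keep[t] <- FALSE
      }
    }
  }
  pos <- pos[keep]; role <- role[keep]; qid <- qid[keep]
  Tn <- length(pos)
  # cleaned observations: RIL heterozygote codes are impossible reads and
  # treated as missing; BC cannot carry the second-parent homozygote
  Gc <- G
  if (type == "RIL" && any(Gc == 1L, na.rm = TRUE)) {
    warning("RIL family contains heterozygote codes; treated as missing")
    Gc[Gc == 1L] <- NA_integer_
  }
  if (type == "BC" && any(Gc == 2L, na.rm = TRUE))
    stop("BC family contains code 2 (second-parent homozygote)")
  # emission matrices (n x ns) per locus; all-ones when unobserved
  emis <- function(t) {
    E <- matrix(1, n, ns)
    if (role[t] > 0L) {
      y <- Gc[, role[t]]
      obs <- !is.na(y)
      if (any(obs)) {
        # observed origin code y -> report class y+1 -> state-space index
        cls <- match(y[obs] + 1L, spec$cols)
        if (anyNA(cls)) stop("genotype code incompatible with family type")
        E[obs, ] <- t(spec$emit[, cls, drop = FALSE])
      }
    }
    E
  }
  trans <- lapply(seq_len(max(Tn - 1, 0)), function(t)
    spec$trans(haldane_r(pos[t + 1] - pos[t])))
  # forward
  al <- vector("list", Tn)
  a <- matrix(spec$init, n, ns, byrow = TRUE) * emis(1)
  a <- a / pmax(rowSums(a), 1e-300)
  al[[1]] <- a
  if (Tn > 1) for (t in 2:Tn) {
    a <- (a %*% trans[[t - 1]]) * emis(t)
    a <- a / pmax(rowSums(a), 1e-300)
    al[[t]] <- a
  }
  # backward + posteriors at query loci
  out <- array(0, c(n, length(qpos), 3L))
  b <- matrix(1, n, ns)
  for (t in Tn:1) {
    if (t < Tn) {
      b <- (b * emis(t + 1)) %*% t(trans[[t]])
      b <- b / pmax(rowSums(b), 1e-300)
    }
    if (qid[t] > 0L) {
      g <- al[[t]] * b
      g <- g / pmax(rowSums(g), 1e-300)
      rep3 <- g %*% spec$report       # n x (2 or 3) report classes
      if (role[t] > 0L) {
        # the genotype is observed here: report it with certainty (the
        # F3 selfing kernel would otherwise smear an observed locus)
        y <- Gc[, role[t]]
        obs <- which(!is.na(y))
        if (length(obs) > 0) {
          rep3[obs, ] <- 0
          rep3[cbind(obs, match(y[obs] + 1L, spec$cols))] <- 1
        }
      }
      out[, qid[t], spec$cols] <- rep3
    }
  }
  out
}
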