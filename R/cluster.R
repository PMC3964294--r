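#' Partition parents by filtering a similarity graph
#'
#' Builds the complete weighted graph whose nodes are the parent lines,
#' removes the edges with a weight below the threshold (or a 0 state when
#' a boolean edge set is given), and takes the transitive closure: the
#' connected components of the kept-edge graph are the ancestral-allele
#' classes.  Class ids are deterministic, numbered by smallest member
#' parent index.
#'
#' @param S symmetric parent x parent similarity matrix, or a symmetric
#'   logical matrix of kept edges when `threshold` is `NULL`.
#' @param threshold edges with `S >= threshold` are kept; set `NULL` if
#'   `S` is already a logical edge matrix.
#' @return integer vector of class ids, one per parent (named when `S`
#'   has dimnames).
#' @export
filter_and_close <- function(S, threshold = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  keep <- if (is.null(threshold)) (S | t(S)) else (S >= threshold)
  diag(keep) <- FALSE
  keep[is.na(keep)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "max")
  comp <- igraph::components(g)$membership
  z <- canonical_classes(as.integer(comp))
  names(z) <- rownames(S)
  z
}

#' Cluster the parent haplotypes along the genome
#'
#' At every scan locus the similarity graph is filtered — either by a
#' fixed threshold (see [empirical_threshold()]) or by the per-pair
#' hidden-Markov classification of the similarity series (see
#' [hmm_classify()]) — and its transitive closure gives the local
#' partition of the parents into ancestral-allele classes.
#'
#' @param field a [similarity_scan()] result.
#' @param method `"threshold"` (default) or `"hmm"`.
#' @param threshold numeric threshold or a `threshold_estimate`
#'   (required for the threshold method).
#' @param candidate_states HMM state counts compared by BIC.
#' @param seed seed for the HMM EM restarts.
#' @return A [local_clustering()].
#' @export
cluster_genome <- function(field, method = c("threshold", "hmm"),
                           threshold = NULL, candidate_states = 2:4,
                           seed = 1) {
  method <- match.arg(method)
  np <- length(field$parents)
  nt <- nrow(field$loci)
  pr <- field$pairs
  if (method == "threshold") {
    if (inherits(threshold, "threshold_estimate")) threshold <- threshold$value
    if (is.null(threshold)) stop("threshold method needs a threshold")
    edges <- field$S >= threshold
  } else {
    if (nt < 10) {
      warning("fewer than 10 scan loci: HMM classification unreliable, ",
              "falling back on the threshold method")
      if (inherits(threshold, "threshold_estimate")) threshold <- threshold$value
      if (is.null(threshold)) stop("threshold fallback needs a threshold")
      edges <- field$S >= threshold
    } else {
      edges <- matrix(FALSE, nt, nrow(pr))
      for (p in seq_len(nrow(pr))) {
        res <- hmm_classify(field$S[, p], candidate_states = candidate_states,
                            seed = seed + p)
        edges[, p] <- res$series == 1L
      }
    }
  }
  assign <- matrix(0L, nt, np, dimnames = list(NULL, field$parents))
  for (t in seq_len(nt)) {
    M <- matrix(FALSE, np, np)
    M[cbind(pr$i, pr$j)] <- edges[t, ]
    assign[t, ] <- filter_and_close(M | t(M), threshold = NULL)
  }
  local_clustering(field$loci, assign)
}
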