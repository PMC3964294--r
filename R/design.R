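#' Construct a multi-cross design
#'
#' Holds the biparental families of a connected design together with the
#' descendant marker genotypes on the family consensus map.  Descendants
#' are coded by parental origin: 0 = homozygote for the first parent's
#' allele, 1 = heterozygote, 2 = homozygote for the second parent's
#' allele, `NA` = missing.
#'
#' @param families data frame with columns `id`, `parent_i`, `parent_j`,
#'   `type` (one of `"F2"`, `"F3"`, `"BC"`, `"RIL"`); one row per family.
#' @param genotypes named list (one element per family id) of integer
#'   matrices, individuals x consensus markers.
#' @param consensus_map the consensus [genetic_map()].
#' @param parents character vector of valid parent names (e.g. a panel's
#'   `$parents`); both parents of every family must belong to it.
#' @return An object of class `cross_design` with elements `families`,
#'   `genotypes`, `map`, `parents`, `n` (per-family sizes), `fam_of`
#'   (family id per stacked individual).  Individuals are stacked in
#'   `families` order; phenotype vectors passed to the modelling
#'   functions must follow that order.
#' @export
cross_design <- function(families, genotypes, consensus_map, parents) {
  stopifnot(is.data.frame(families),
            all(c("id", "parent_i", "parent_j", "type") %in% names(families)))
  families$id <- as.character(families$id)
  families$type <- match.arg(families$type,
                             c("F2", "F3", "BC", "RIL"), several.ok = TRUE)
  bad <- setdiff(c(families$parent_i, families$parent_j), parents)
  if (length(bad) > 0)
    stop("family parent(s) not in the panel: ", paste(bad, collapse = ", "))
  if (!setequal(names(genotypes), families$id))
    stop("genotype list does not match family ids")
  nmk <- n_markers(consensus_map)
  genotypes <- genotypes[families$id]
  for (id in families$id) {
    G <- genotypes[[id]]
    if (!is.matrix(G) || ncol(G) != nmk)
      stop("family ", id, ": genotype matrix must have ", nmk, " columns")
    if (nrow(G) < 1) stop("family ", id, ": no individuals")
    if (any(!(G %in% c(0L, 1L, 2L, NA))))
      stop("family ", id, ": genotype codes must be 0, 1, 2 or NA")
  }
  n <- vapply(genotypes, nrow, integer(1))
  structure(list(families = families, genotypes = genotypes,
                 map = consensus_map, parents = parents, n = n,
                 fam_of = rep(families$id, n)),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("Multi-cross design:", nrow(x$families), "families,",
      sum(x$n), "individuals,", length(unique(c(x$families$parent_i,
                                                x$families$parent_j))),
      "parents involved\n")
  for (k in seq_len(nrow(x$families)))
    cat(sprintf("  %s: %s x %s (%s, n = %d)\n", x$families$id[k],
                x$families$parent_i[k], x$families$parent_j[k],
                x$families$type[k], x$n[k]))
  invisible(x)
}
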