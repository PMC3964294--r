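#' Construct a per-locus clustering of parent lines
#'
#' At each scan locus the parents are partitioned into ancestral-allele
#' classes.  Class ids are canonical: classes are numbered in order of
#' their smallest member parent index, so two clusterings describing the
#' same partitions have identical ids.
#'
#' @param loci data frame with columns `chrom`, `pos` (one row per scan
#'   locus).
#' @param assign integer matrix, loci in rows, parents in columns
#'   (colnames = parent names); `assign[t, i]` is the class of parent `i`
#'   at locus `t`.
#' @return An object of class `local_clustering` with elements `loci`,
#'   `assign`, `n_classes` (integer per locus), `parents`.
#' @export
local_clustering <- function(loci, assign) {
  stopifnot(is.data.frame(loci), is.matrix(assign),
            nrow(loci) == nrow(assign))
  if (is.null(colnames(assign))) stop("assign needs parent column names")
  parents <- colnames(assign)
  assign <- t(apply(assign, 1, canonical_classes))
  if (nrow(loci) == 1) assign <- matrix(assign, nrow = 1)
  colnames(assign) <- parents
  storage.mode(assign) <- "integer"
  structure(list(loci = loci, assign = assign,
                 n_classes = apply(assign, 1, function(z) length(unique(z))),
                 parents = colnames(assign)),
            class = "local_clustering")
}

# renumber class labels so that classes appear in order of smallest member
canonical_classes <- function(z) {
  match(z, unique(z))
}

#' @export
print.local_clustering <- function(x, ...) {
  s <- clustering_summary(x)
  cat("Local clustering:", nrow(x$loci), "loci,", length(x$parents),
      "parents\n")
  cat(sprintf("  mean ancestral alleles: %.2f; clustering changes: %d\n",
              s$mean_n_classes, s$n_changes))
  invisible(x)
}

#' @export
summary.local_clustering <- function(object, ...) {
  s <- clustering_summary(object)
  structure(c(s, list(n_loci = nrow(object$loci),
                      n_parents = length(object$parents))),
            class = "summary.local_clustering")
}

#' @export
print.summary.local_clustering <- function(x, ...) {
  cat("Per-locus ancestral-allele clustering\n")
  cat("  loci:", x$n_loci, " parents:", x$n_parents, "\n")
  cat(sprintf("  mean number of classes: %.3f\n", x$mean_n_classes))
  cat("  clustering changes between consecutive loci:", x$n_changes, "\n")
  invisible(x)
}

#' Summarize a local clustering
#'
#' Returns the mean per-locus number of ancestral-allele classes and the
#' number of clustering changes, i.e. consecutive locus pairs whose
#' partitions differ.  Partitions are compared as set partitions: class
#' labels are ignored.
#'
#' @param lc a [local_clustering()].
#' @return list with `mean_n_classes` and `n_changes`.
#' @export
clustering_summary <- function(lc) {
  a <- lc$assign
  n_changes <- 0L
  if (nrow(a) > 1) {
    # rows are canonical, so partition equality == label equality
    same <- rowSums(a[-1, , drop = FALSE] != a[-nrow(a), , drop = FALSE]) == 0
    n_changes <- sum(!same)
  }
  list(mean_n_classes = mean(lc$n_classes), n_changes = as.integer(n_changes))
}

#' Write / read a clustering as XML
#'
#' Self-describing XML with one `<locus>` record per scan position, each
#' holding `<class>` elements listing member `<parent>` lines:
#' `<clustering><locus chr pos><class id><parent name/></class></locus></clustering>`.
#' `read_clustering_xml(write_clustering_xml(x))` restores the identical
#' partition at every locus.
#'
#' @param lc a [local_clustering()].
#' @param path output file path.
#' @return `write_clustering_xml` returns `path` invisibly;
#'   `read_clustering_xml` returns a [local_clustering()].
#' @export
write_clustering_xml <- function(lc, path) {
  doc <- xml2::xml_new_root("clustering")
  for (t in seq_len(nrow(lc$loci))) {
    lnode <- xml2::xml_add_child(doc, "locus",
                                 chr = as.character(lc$loci$chrom[t]),
                                 pos = format(lc$loci$pos[t], digits = 15))
    z <- lc$assign[t, ]
    for (cl in sort(unique(z))) {
      cnode <- xml2::xml_add_child(lnode, "class", id = as.character(cl))
      for (p in lc$parents[z == cl])
        xml2::xml_add_child(cnode, "parent", name = p)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_clustering_xml
#' @param parents optional character vector of expected parent names; an
#'   error is raised if the file mentions a parent not in this set.
#' @export
read_clustering_xml <- function(path, parents = NULL) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "clustering") stop("not a clustering XML file")
  lnodes <- xml2::xml_find_all(doc, "locus")
  if (length(lnodes) == 0) stop("clustering XML contains no locus records")
  first <- TRUE
  all_parents <- NULL
  rows <- vector("list", length(lnodes))
  loci <- data.frame(chrom = character(length(lnodes)),
                     pos = numeric(length(lnodes)),
                     stringsAsFactors = FALSE)
  for (t in seq_along(lnodes)) {
    ln <- lnodes[[t]]
    loci$chrom[t] <- xml2::xml_attr(ln, "chr")
    loci$pos[t] <- as.numeric(xml2::xml_attr(ln, "pos"))
    cls <- xml2::xml_find_all(ln, "class")
    nm <- character(0); id <- integer(0)
    for (cn in cls) {
      members <- xml2::xml_attr(xml2::xml_find_all(cn, "parent"), "name")
      nm <- c(nm, members)
      id <- c(id, rep(as.integer(xml2::xml_attr(cn, "id")), length(members)))
    }
    if (anyNA(id) || anyNA(nm) || anyDuplicated(nm))
      stop("malformed clustering XML at locus ", t)
    if (first) {
      all_parents <- if (!is.null(parents) && setequal(nm, parents))
        parents else sort(nm)
      first <- FALSE
    }
    if (!setequal(nm, all_parents))
      stop("locus ", t, " does not cover the same parent set")
    if (!is.null(parents) && !all(nm %in% parents))
      stop("unknown parent name(s) in clustering file: ",
           paste(setdiff(nm, parents), collapse = ", "))
    rows[[t]] <- id[match(all_parents, nm)]
  }
  assign <- do.call(rbind, rows)
  colnames(assign) <- all_parents
  local_clustering(loci, assign)
}
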