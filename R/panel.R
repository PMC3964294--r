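#' Construct a haplotype panel
#'
#' A haplotype panel holds the marker alleles of the inbred parent lines
#' of a multi-cross design.  Parents are fully homozygous so one row of
#' integer allele codes per line describes its haplotype; `NA` encodes a
#' missing genotype.
#'
#' @param alleles integer matrix, parents in rows (rownames = parent
#'   names), markers in columns in map order.
#' @param map the parent-line [genetic_map()]; must have exactly
#'   `ncol(alleles)` markers.
#' @return An object of class `haplotype_panel` with elements `alleles`
#'   and `map`.
#' @export
haplotype_panel <- function(alleles, map) {
  stopifnot(is.matrix(alleles))
  if (is.null(rownames(alleles))) stop("allele matrix needs parent row names")
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != n_markers(map))
    stop("allele matrix has ", ncol(alleles), " columns but the map has ",
         n_markers(map), " markers")
  if (any(alleles < 0, na.rm = TRUE)) stop("allele codes must be >= 0 or NA")
  colnames(alleles) <- map$markers$marker
  structure(list(alleles = alleles, map = map,
                 parents = rownames(alleles)),
            class = "haplotype_panel")
}

#' Read a parent genotype matrix
#'
#' Tab-separated text, one row per parent line (first column = parent
#' name), one column per marker with a header of marker names matching
#' the map; `NA` for missing.
#'
#' @param path file path.
#' @param map parent-line [genetic_map()].
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE)
  mk <- map$markers$marker
  if (!all(mk %in% colnames(df)))
    stop("genotype file is missing markers present in the map")
  haplotype_panel(as.matrix(df[, mk, drop = FALSE]), map)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$alleles), "parent lines x",
      ncol(x$alleles), "markers;",
      sum(is.na(x$alleles)), "missing calls\n")
  invisible(x)
}

#' Whole-genome alike-in-state kinship
#'
#' The default kinship coefficient between two haplotypes is the
#' proportion of alike-in-state alleles over the markers observed in
#' both, using all markers of the genome.  A pair with no jointly
#' observed marker gets K = 0 with a warning.
#'
#' @param panel a [haplotype_panel()].
#' @return symmetric parent x parent matrix in \[0, 1\], unit diagonal.
#' @export
default_kinship <- function(panel) {
  A <- panel$alleles
  n <- nrow(A)
  obs <- !is.na(A)
  K <- matrix(1, n, n, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(n)) {
    ni <- sum(obs[i, ])
    K[i, i] <- if (ni > 0) sum(A[i, obs[i, ]] == A[i, obs[i, ]]) / ni else 1
    if (i < n) for (j in (i + 1):n) {
      both <- obs[i, ] & obs[j, ]
      m <- sum(both)
      if (m == 0) {
        warning("parents ", rownames(A)[i], " and ", rownames(A)[j],
                " share no observed marker; kinship set to 0")
        K[i, j] <- K[j, i] <- 0
      } else {
        K[i, j] <- K[j, i] <- sum(A[i, both] == A[j, both]) / m
      }
    }
  }
  K
}
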