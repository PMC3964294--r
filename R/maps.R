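#' Construct a genetic map
#'
#' A genetic map is an ordered set of markers per chromosome with positions
#' in centimorgans.  Positions must be non-decreasing within a chromosome
#' and marker names unique genome-wide.
#'
#' @param df data frame with columns `chrom`, `marker`, `pos` (cM). Rows
#'   may be in any order; they are sorted by position within chromosome,
#'   chromosomes kept in order of first appearance.
#' @return An object of class `genetic_map`: a list with element
#'   `markers`, a data frame (`chrom`, `marker`, `pos`) sorted by
#'   chromosome and position.
#' @export
genetic_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "marker", "pos") %in% names(df)))
  df <- df[, c("chrom", "marker", "pos")]
  df$chrom <- as.character(df$chrom)
  df$marker <- as.character(df$marker)
  df$pos <- as.numeric(df$pos)
  if (anyNA(df$pos) || any(df$pos < 0))
    stop("marker positions must be non-negative numbers")
  if (anyDuplicated(df$marker))
    stop("duplicate marker name(s): ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  chroms <- unique(df$chrom)
  # positions must already be monotone within the file order of each chromosome
  for (ch in chroms) {
    p <- df$pos[df$chrom == ch]
    if (is.unsorted(p))
      stop("non-monotone marker positions on chromosome ", ch)
  }
  ord <- order(match(df$chrom, chroms), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(markers = df), class = "genetic_map")
}

#' Read a genetic map from a delimited text file
#'
#' Expects a header line with columns `chrom`, `marker`, `pos` (cM).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  genetic_map(df)
}

#' @export
print.genetic_map <- function(x, ...) {
  m <- x$markers
  cat("Genetic map:", length(unique(m$chrom)), "chromosome(s),",
      nrow(m), "markers\n")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    cat(sprintf("  %s: %d markers, %.1f-%.1f cM\n", ch, length(p),
                min(p), max(p)))
  }
  invisible(x)
}

map_chromosomes <- function(map) unique(map$markers$chrom)

n_markers <- function(map) nrow(map$markers)

chrom_markers <- function(map, chrom) {
  map$markers[map$markers$chrom == chrom, , drop = FALSE]
}

#' Align a parent-line map with a family consensus map
#'
#' Markers shared by name between the two maps anchor a per-chromosome
#' monotone piecewise-linear transfer of coordinates in both directions.
#' At least two anchors per chromosome are required and their order must
#' be identical on both maps.  Between anchors the transfer interpolates
#' linearly; beyond the terminal anchors it extrapolates with the nearest
#' segment's slope, which keeps the transfer monotone.
#'
#' @param parent_map,consensus_map [genetic_map()] objects.
#' @return An object of class `map_alignment`: per chromosome the anchor
#'   table (`marker`, `pos_parent`, `pos_consensus`).
#' @seealso [transfer_position()]
#' @export
align_maps <- function(parent_map, consensus_map) {
  pm <- parent_map$markers
  cm <- consensus_map$markers
  chroms <- intersect(unique(pm$chrom), unique(cm$chrom))
  if (length(chroms) == 0) stop("maps share no chromosome")
  anchors <- lapply(chroms, function(ch) {
    p <- pm[pm$chrom == ch, ]
    c2 <- cm[cm$chrom == ch, ]
    shared <- intersect(p$marker, c2$marker)
    if (length(shared) < 2)
      stop("chromosome ", ch, ": fewer than 2 anchor markers ",
           "(at least two markers per chromosome are mandatory)")
    a <- data.frame(marker = shared,
                    pos_parent = p$pos[match(shared, p$marker)],
                    pos_consensus = c2$pos[match(shared, c2$marker)],
                    stringsAsFactors = FALSE)
    a <- a[order(a$pos_parent), , drop = FALSE]
    if (is.unsorted(a$pos_consensus))
      stop("chromosome ", ch, ": anchor markers are not colinear ",
           "between the two maps (they have to be roughly colinear)")
    # drop anchors duplicated at a position (vertical/horizontal segments)
    keep <- !duplicated(a$pos_parent) & !duplicated(a$pos_consensus)
    a <- a[keep, , drop = FALSE]
    if (nrow(a) < 2)
      stop("chromosome ", ch, ": fewer than 2 distinct anchor positions")
    rownames(a) <- NULL
    a
  })
  names(anchors) <- chroms
  structure(list(anchors = anchors), class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat("Map alignment:", length(x$anchors), "chromosome(s)\n")
  for (ch in names(x$anchors))
    cat(sprintf("  %s: %d anchors\n", ch, nrow(x$anchors[[ch]])))
  invisible(x)
}

#' Transfer positions between aligned maps
#'
#' Piecewise-linear interpolation between anchors, linear extrapolation
#' beyond terminal anchors using the nearest segment's slope.
#'
#' @param alignment a [align_maps()] result.
#' @param chrom chromosome name.
#' @param pos numeric vector of positions (cM).
#' @param from coordinate system of `pos`: `"consensus"` (default) or
#'   `"parent"`.
#' @return numeric vector of transferred positions.
#' @export
transfer_position <- function(alignment, chrom, pos,
                              from = c("consensus", "parent")) {
  from <- match.arg(from)
  a <- alignment$anchors[[chrom]]
  if (is.null(a)) stop("chromosome ", chrom, " not in alignment")
  if (from == "consensus") {
    x <- a$pos_consensus; y <- a$pos_parent
  } else {
    x <- a$pos_parent; y <- a$pos_consensus
  }
  out <- stats::approx(x, y, xout = pos, rule = 1)$y
  # extrapolate with nearest segment slope
  n <- length(x)
  lo <- pos < x[1]
  hi <- pos > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (pos[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (pos[hi] - x[n])
  }
  out
}

#' Build the genome scan grid
#'
#' The scan grid is the union of every consensus-map marker position and a
#' ladder of step-spaced loci from the first to the last marker of each
#' chromosome, sorted and deduplicated (1e-9 cM tolerance).
#'
#' @param consensus_map a [genetic_map()].
#' @param step_cM positive progression step in cM.
#' @return An object of class `scan_grid`: data frame `loci` with columns
#'   `chrom`, `pos`, plus `step_cM`.
#' @export
build_scan_grid <- function(consensus_map, step_cM) {
  if (!is.numeric(step_cM) || length(step_cM) != 1 || step_cM <= 0)
    stop("step_cM must be a positive number")
  m <- consensus_map$markers
  loci <- do.call(rbind, lapply(unique(m$chrom), function(ch) {
    p <- m$pos[m$chrom == ch]
    lad <- seq(min(p), max(p), by = step_cM)
    # always include chromosome end
    pos <- sort(c(p, lad, max(p)))
    pos <- pos[c(TRUE, diff(pos) > 1e-9)]
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  structure(list(loci = loci, step_cM = step_cM), class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat("Scan grid:", nrow(x$loci), "loci, step", x$step_cM, "cM\n")
  invisible(x)
}
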