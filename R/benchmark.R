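#' Set up a synthetic multi-cross benchmark
#'
#' Builds the full analysis state for simulation studies: a parent panel
#' descending from a few ancestors, a thinned consensus map, the map
#' alignment, the scan grid, the extended-similarity field, a clustering
#' threshold from a null sampler and the per-locus clustering.
#'
#' The defaults emulate a breeding design of 12 related parent lines on
#' one 150 cM chromosome with 1 cM parent markers, a 5 cM consensus map
#' and a 1 cM scan step.  The ancestor count (10) is calibrated so the
#' realized mean number of ancestral-allele classes is close to 5.8, the
#' level observed in comparable real 12-parent designs; mosaic
#' generations (5) give ancestral blocks long relative to the 20 cM
#' window, as in highly related breeding panels.
#'
#' @param seed integer seed.
#' @param n_ancestors,n_parents,chr_length_cM,marker_step_cM,generations
#'   see [simulate_parent_panel()].
#' @param consensus_step_cM consensus-map marker spacing.
#' @param scan_step_cM scan-grid progression step.
#' @param n_families,family_size,type see [design_families()].
#' @param window_cM similarity window length.
#' @param sampler `"equilibrium"` (default) or `"mosaic"` null sampler
#'   for the clustering threshold.
#' @param cluster_alpha type I error of the clustering threshold.
#' @param null_reps repetitions of the null sampler.
#' @param generations_null mosaic generations for the mosaic sampler.
#' @return list with `panel`, `truth`, `consensus_map`, `alignment`,
#'   `grid`, `field`, `null`, `threshold`, `clustering`, `fam_table`.
#' @export
setup_benchmark <- function(seed = 1, n_ancestors = 10, n_parents = 12,
                            chr_length_cM = 150, marker_step_cM = 1,
                            generations = 5, consensus_step_cM = 5,
                            scan_step_cM = 1, n_families = 8,
                            family_size = 60, type = "F2", window_cM = 20,
                            sampler = c("equilibrium", "mosaic"),
                            cluster_alpha = 0.05, null_reps = 200,
                            generations_null = 500) {
  sampler <- match.arg(sampler)
  sim <- simulate_parent_panel(n_ancestors, n_parents, chr_length_cM,
                               marker_step_cM, generations, seed = seed)
  consensus_map <- thin_map(sim$panel$map, consensus_step_cM)
  alignment <- align_maps(sim$panel$map, consensus_map)
  grid <- build_scan_grid(consensus_map, scan_step_cM)
  field <- similarity_scan(sim$panel, grid, window_cM = window_cM,
                           alignment = alignment)
  null <- if (sampler == "equilibrium")
    equilibrium_null(sim$panel, grid, window_cM = window_cM,
                     n_reps = null_reps, alignment = alignment,
                     seed = seed + 101)
  else
    mosaic_null(sim$panel, grid, window_cM = window_cM,
                generations = generations_null, n_reps = null_reps,
                alignment = alignment, seed = seed + 101)
  threshold <- empirical_threshold(null, cluster_alpha)
  clustering <- cluster_genome(field, "threshold", threshold)
  fam_table <- design_families(sim$panel, n_families, family_size, type)
  list(panel = sim$panel, truth = sim$truth, consensus_map = consensus_map,
       alignment = alignment, grid = grid, field = field, null = null,
       threshold = threshold, clustering = clustering, fam_table = fam_table)
}

# simulate one data set of the benchmark and return analysis-ready parts
.bench_dataset <- function(bench, qtl, seed) {
  dat <- simulate_family_data(bench$fam_table, bench$panel,
                              bench$consensus_map, qtl = qtl, seed = seed)
  probs <- suppressWarnings(genotype_probabilities(dat$design, bench$grid))
  list(y = dat$pheno, probs = probs)
}

#' Genome-wide null calibration of the permutation threshold
#'
#' Simulates no-QTL data sets from the benchmark design, computes each
#' replicate's within-family permutation threshold for the connected
#' model, and reports how often the observed genome-wide maximum
#' `-log10(p)` exceeds it — the realized genome-wide type I error.
#'
#' @param bench a [setup_benchmark()] result.
#' @param n_replicates number of simulated null data sets.
#' @param n_perm permutations per replicate.
#' @param alpha nominal genome-wide type I error.
#' @param seed integer seed.
#' @return list with `rate`, `alpha`, `n_replicates`, `rejections`.
#' @export
null_rejection_rate <- function(bench, n_replicates = 200, n_perm = 200,
                                alpha = 0.10, seed = 1) {
  rej <- logical(n_replicates)
  for (b in seq_len(n_replicates)) {
    ds <- .bench_dataset(bench, qtl = NULL, seed = seed + 7919L * b)
    blocks <- locus_blocks(ds$probs, NULL)
    thr <- permutation_threshold(ds$y, ds$probs, NULL, n_perm = n_perm,
                                 alpha = alpha, seed = seed + 104729L + b,
                                 blocks = blocks)
    obs <- .scan_maxima(matrix(ds$y, ncol = 1), ds$probs, NULL, blocks)
    rej[b] <- obs > thr$threshold
  }
  list(rate = mean(rej), alpha = alpha, n_replicates = n_replicates,
       rejections = sum(rej))
}

#' Compare power and precision of the connected and LD models
#'
#' Runs the simulation protocol on a benchmark design: a single biallelic
#' additive QTL is placed at each of `n_positions` scan loci spread along
#' the chromosome; the parents of the biggest ancestral-allele class at
#' that locus carry the mutated allele; each position is replicated
#' `n_reps` times; every data set is analysed with the connected
#' (per-parent) and the LD (per-cluster) models by iterative cofactor
#' detection at a design-level permutation threshold; detections feed a
#' power/precision report ([evaluate_detections()]).
#'
#' @param bench a [setup_benchmark()] result.
#' @param n_positions number of simulated QTL positions.
#' @param n_reps replicates per position.
#' @param effect additive effect of the mutated allele (phenotype s.d.
#'   units; residual is N(0, 1)).
#' @param alpha genome-wide type I error of the detection threshold.
#' @param n_perm permutations for the design-level thresholds.
#' @param exclusion_cM cofactor exclusion window (default 10).
#' @param intervals precision intervals in cM.
#' @param seed integer seed.
#' @return An `evaluate_detections()` report plus (as attributes)
#'   `thresholds` — the per-model permutation thresholds.
#' @export
power_precision_benchmark <- function(bench, n_positions = 20, n_reps = 20,
                                      effect = 0.25, alpha = 0.10,
                                      n_perm = 1000, exclusion_cM = 10,
                                      intervals = c(1, 2, 5, 10),
                                      seed = 1) {
  loci <- bench$grid$loci
  ch <- loci$chrom[1]
  cand <- which(loci$chrom == ch)
  pos_idx <- cand[unique(round(seq(1, length(cand),
                                   length.out = n_positions)))]
  truth <- loci$pos[pos_idx]

  # design-level thresholds from one null data set per model, as in a
  # real analysis where the threshold is computed once per design
  ds0 <- .bench_dataset(bench, qtl = NULL, seed = seed + 424243L)
  thr <- list(
    connected = permutation_threshold(ds0$y, ds0$probs, NULL,
                                      n_perm = n_perm, alpha = alpha,
                                      seed = seed + 1)$threshold,
    ld = permutation_threshold(ds0$y, ds0$probs, bench$clustering,
                               n_perm = n_perm, alpha = alpha,
                               seed = seed + 2)$threshold)

  det <- list(connected = vector("list", length(pos_idx)),
              ld = vector("list", length(pos_idx)))
  for (q in seq_along(pos_idx)) {
    tq <- pos_idx[q]
    mutant <- assign_qtl_alleles(bench$clustering, tq,
                                 seed = seed + 31L * q)
    qtl <- list(chrom = ch, pos = loci$pos[tq], effect = effect,
                mutant = mutant)
    det$connected[[q]] <- vector("list", n_reps)
    det$ld[[q]] <- vector("list", n_reps)
    for (rp in seq_len(n_reps)) {
      ds <- .bench_dataset(bench, qtl = qtl,
                           seed = seed + 5000L * q + rp)
      for (m in c("connected", "ld")) {
        clus <- if (m == "ld") bench$clustering else NULL
        fit <- detect_qtl(ds$y, ds$probs, clus, thr[[m]],
                          exclusion_cM = exclusion_cM)
        det[[m]][[q]][[rp]] <- fit$qtl$pos
      }
    }
  }
  rep <- evaluate_detections(det, truth, intervals)
  attr(rep, "thresholds") <- thr
  attr(rep, "effect") <- effect
  rep
}
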