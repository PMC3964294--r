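# small in-code fixtures shared across test files

# one-chromosome map with markers at the given positions
fix_map <- function(pos, chrom = "1", prefix = "m") {
  genetic_map(data.frame(chrom = chrom,
                         marker = paste0(prefix, seq_along(pos)),
                         pos = pos))
}

# panel from an allele matrix on a regular map (1 cM spacing by default)
fix_panel <- function(A, pos = seq(0, by = 1, length.out = ncol(A))) {
  if (is.null(rownames(A))) rownames(A) <- paste0("P", seq_len(nrow(A)))
  haplotype_panel(A, fix_map(pos))
}

# write a map TSV and return its path
fix_map_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

const1 <- function() make_weight_function("constant1", 1e6)
const0 <- function() make_weight_function("constant0", 1e6)

# a small cached benchmark shared by the modelling tests (6 parents,
# 4 F2 families of 30 on one 60 cM chromosome)
.bench_cache <- new.env(parent = emptyenv())
small_bench <- function() {
  if (is.null(.bench_cache$b))
    .bench_cache$b <- setup_benchmark(seed = 202, n_ancestors = 4,
                                      n_parents = 6, chr_length_cM = 60,
                                      marker_step_cM = 1,
                                      consensus_step_cM = 2,
                                      n_families = 4, family_size = 30,
                                      null_reps = 50)
  .bench_cache$b
}

# simulate one analysis-ready data set from a bench fixture
bench_data <- function(bench, qtl = NULL, seed = 1) {
  dat <- simulate_family_data(bench$fam_table, bench$panel,
                              bench$consensus_map, qtl = qtl, seed = seed)
  probs <- suppressWarnings(genotype_probabilities(dat$design, bench$grid))
  list(y = dat$pheno, probs = probs, design = dat$design)
}
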