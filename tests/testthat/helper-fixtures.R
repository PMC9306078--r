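# Shared fixtures: small, fast study configurations and code helpers.

# genotype integer matrix (0/1/2 B alleles) -> call codes
geno_codes <- function(genotypes) {
  matrix(c("A", "H", "B")[genotypes + 1L], nrow = nrow(genotypes),
         dimnames = dimnames(genotypes))
}

# a compact 3-group genome for fast linkage/QTL tests
small_config <- function(seed = 1, ...) {
  sim_config(n_individuals = 150, n_linkage_groups = 3, markers_per_group = 12,
             marker_spacing = 8,
             qtl_spec = list(list(group = 2, position = 40,
                                  additive = -7.19, dominance = -3.28)),
             seed = seed, ...)
}

# study-regime genome (defaults) with a chosen seed
study_config <- function(seed = 1, ...) sim_config(seed = seed, ...)

# depth_matrix restricted to the first k markers
subset_depths <- function(depths, k) {
  out <- list(counts = depths$counts[seq_len(k), , drop = FALSE],
              parent1_counts = depths$parent1_counts[seq_len(k)],
              parent2_counts = depths$parent2_counts[seq_len(k)],
              source_parent = depths$source_parent[seq_len(k)])
  class(out) <- "depth_matrix"
  out
}
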