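# Shared fixtures: all built in code at test time.

# Small, fast synthetic cohort for unit/integration tests.
small_config <- function(seed = 42, ...) {
  synth_config(n_patients = 24, n_genes = 600, n_chromosomes = 4,
               n_planted_regions = 4, planted_region_gene_span = 15,
               n_planted_drivers = 4, neighbor_fanout = 8,
               planted_carrier_fraction = 0.25, seed = seed, ...)
}

# Probe map for a single synthetic chromosome with 1 kb probe spacing.
chr1_probe_map <- function(n) {
  data.frame(probe = sprintf("p%05d", seq_len(n)), chrom = "chr1",
             pos = seq_len(n) * 1000L, stringsAsFactors = FALSE)
}

# Fabricated expression object with explicit scaled values / ranks, for
# tests that exercise AGS or concordance logic directly.
fake_expr <- function(scaled, ranks = NULL) {
  if (is.null(ranks)) {
    ranks <- t(apply(scaled, 1, rank, ties.method = "average"))
    dimnames(ranks) <- dimnames(scaled)
  }
  structure(list(values = 2^scaled, log2 = scaled, scaled = scaled,
                 ranks = ranks), class = "expression_matrix")
}

# Minimal fgs-like object from an alteration table (gene, patient, state).
fake_fgs <- function(genes, alterations) {
  structure(list(genes = genes, alterations = alterations,
                 tests = NULL, annotation = NULL, regions = NULL),
            class = "fgs")
}
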