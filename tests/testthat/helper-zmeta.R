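# Shared builders for the test suite.

ztab <- function(genes, z, n = 1L, label = "t") {
  signed_z_table(genes, z, n, label = label)
}

# A random signed-Z table over a shared toy gene universe.
random_ztab <- function(n = 20, label = "t", genes = sprintf("G%03d", 1:n)) {
  ztab(genes, rnorm(n), sample(1:5, n, replace = TRUE), label = label)
}

# A small truth with one configurable planted effect.
toy_truth <- function(n_genes = 10, seed = 1) {
  generate_truth(n_genes = n_genes, n_effect_per_contrast = 0, n_hubs = 0,
                 seed = seed)
}

# Minimal study summary built directly from vectors.
toy_study <- function(id, type, genes, p, dir,
                      contrast = "normal_vs_tumor", n1 = 10, n2 = 10) {
  study_summary(id, type, contrast, genes, p, dir, n1 = n1, n2 = n2)
}
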