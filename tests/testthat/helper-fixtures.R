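# Shared fixtures, built in code. Heavier objects are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

toy_motifs <- function() default_motif_library()

# a small simulated genome with ground truth (about 25 kb)
small_sim <- function() cached("small_sim", {
  generate_random_genome(synthetic_genome_spec(n_genes = 12, n_chrom = 2,
                                               seed = 101))
})

# a second, independently seeded genome from the same conditions
small_sim2 <- function() cached("small_sim2", {
  generate_random_genome(synthetic_genome_spec(n_genes = 8, n_chrom = 2,
                                               seed = 202))
})

# light initiation classifier trained on small_sim (used by several tests)
micro_init_classifier <- function() cached("micro_init", {
  g <- small_sim()
  sets <- make_training_sets(g$genome, g$annotations)
  scheme <- default_initiation_scheme()
  specs <- default_initiation_specs()
  fx <- extract_feature_matrix(g$genome, sets$initiation, scheme, specs,
                               toy_motifs())
  ens <- train_ensemble(fx, sets$initiation$label, sets$initiation$chrom,
                        ensemble_config(replicates_per_fold = 1,
                                        trees_per_forest = 20, seed = 9))
  list(ensemble = ens, scheme = scheme, specs = specs,
       features = fx, anchors = sets$initiation)
})

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
  path
}
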