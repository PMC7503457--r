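# Small cohort builders shared across test files.

small_cohort <- function(seed = 1, n_samples = 120, n_planted = 5,
                         n_decoy = 40, ...) {
  generate_cohort(generator_config(
    n_samples = n_samples, n_planted = n_planted, n_decoy_lnc = n_decoy,
    n_decoy_mir = n_decoy, n_decoy_mrna = n_decoy, seed = seed, ...))
}

preprocessed_layers <- function(cohort, ...) {
  pp <- preprocess_layers(list(lnc = cohort$lnc_layer, mir = cohort$mir_layer,
                               mrna = cohort$mrna_layer),
                          purity = cohort$purity, ...)
  pp[c("lnc", "mir", "mrna")]
}

# A bare expression layer from a named list of per-sample vectors.
layer_from_vectors <- function(vectors, layer_class, sample_ids = NULL) {
  m <- do.call(rbind, vectors)
  if (!is.null(sample_ids)) colnames(m) <- sample_ids
  expression_layer(m, layer_class, is_log2 = TRUE)
}

toy_dir <- function() {
  d <- system.file("extdata", "toy", package = "lncperturb")
  if (!nzchar(d)) stop("toy fixture not installed")
  d
}
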