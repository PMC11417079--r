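# Scaled-down study conditions used by the training-dependent tests:
# a light U-Net preset (widths [16, 16, 32, 64]) trained on 250
# corpus-driven 32 x 32 series, evaluated on 50-series held-out corpus
# and urand test sets.  Training runs once per test session and is
# memoized here; every consumer shares the same models and datasets.
.trained_cache <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (!is.null(.trained_cache$study)) return(.trained_cache$study)
  corpus <- procedural_corpus(600, size = 32, seed = 100)
  train_ds <- build_synthetic_dataset(
    synth_config(250, size = 32, mode = "corpus", seed = 101), corpus[1:500])
  test_corpus <- build_synthetic_dataset(
    synth_config(50, size = 32, mode = "corpus", seed = 202), corpus[501:600])
  test_urand <- build_synthetic_dataset(
    synth_config(50, size = 32, mode = "urand", seed = 303))
  cnn <- build_cnn(channels = c(16L, 16L, 32L, 64L), seed = 7)
  cnn <- train_model(cnn, train_ds, train_config(epochs = 60, batch = 25, seed = 8))
  nn1d <- build_nn1d(seed = 9)
  nn1d <- train_model(nn1d, train_ds,
                      train_config(epochs = 5, batch = 10000, seed = 10))
  .trained_cache$study <- list(train = train_ds, test_corpus = test_corpus,
                               test_urand = test_urand, cnn = cnn, nn1d = nn1d)
  .trained_cache$study
}

# per-series median absolute T error of an estimator over a dataset
per_slice_abs_err <- function(dataset, estimate) {
  vapply(dataset$records, function(rec) {
    pm <- estimate(rec$series)
    median(abs(pm$t - rec$truth$t))
  }, numeric(1))
}
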