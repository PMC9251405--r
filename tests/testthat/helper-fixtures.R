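# Shared fixtures, trained once per test run.

.fixtures <- new.env(parent = emptyenv())

# small trained model: 3 classes x 2 variants (all training), N = 30,
# 2000 epochs -- used for recognition/completion contracts
tiny_fit <- function() {
  if (is.null(.fixtures$tiny)) {
    ds <- build_dataset(0, shape_classes()[1:3], n_per_class = 2L, n_train = 2L)
    cfg <- training_config(max_epochs = 2000L, patience_epochs = 2000L,
                           learning_rate = 1e-3, n_context = 30L, seed = 0L)
    .fixtures$tiny <- list(dataset = ds, model = train_sctrnn(ds, cfg))
  }
  .fixtures$tiny
}

# the full scaled-down study (2 networks, 3 classes, 10 variants each,
# 9-cell sweep) -- the end-to-end acceptance surface
study_fixture <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- run_precision_study(seed = 1L)
  }
  .fixtures$study
}

# a quickly trained single-class model for cheap sweep/plumbing tests
quick_fit <- function() {
  if (is.null(.fixtures$quick)) {
    ds <- build_dataset(3, shape_classes()[1], n_per_class = 3L, n_train = 2L)
    cfg <- training_config(max_epochs = 150L, patience_epochs = 150L,
                           n_context = 10L, seed = 4L)
    .fixtures$quick <- list(dataset = ds, model = train_sctrnn(ds, cfg))
  }
  .fixtures$quick
}
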