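# Shared fixtures. The end-to-end fixture (default synthetic cohort +
# trained classifier on a stratified 70/30 split) is built once, lazily,
# and reused across test files so the suite trains a single model.

small_design <- function(seed = 1L, ...) {
  simulation_design(n_genes = 300L, n_samples = 40L, n_classes = 2L,
                    n_sets = 12L, set_size = 15L,
                    active_sets_per_class = list(C1 = 1:2, C2 = 3:4),
                    seed = seed, ...)
}

small_arch <- function(n_sets = 12L, n_classes = 2L) {
  architecture_spec(n_sets, n_classes, hidden_dims = c(16L, 8L))
}

fast_config <- function(epochs = 60L, seed = 11L) {
  training_config(epochs = epochs, batch_size = 16L, seed = seed)
}

e2e_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    design <- simulation_design(seed = 7L)
    cohort <- make_cohort(design)
    set.seed(99L)
    split <- subspectra:::stratified_split(cohort$labels, 0.3)
    arch <- architecture_spec(design$n_sets, design$n_classes,
                              hidden_dims = c(200L, 50L, 12L, 10L))
    config <- training_config(epochs = 250L, batch_size = 32L, seed = 42L)
    model <- train_classifier(cohort$expr[, split$train],
                              cohort$labels[split$train],
                              cohort$collection, arch, config)
    holdout_expr <- cohort$expr[, split$test]
    holdout_pred <- predict_expression(model, holdout_expr)
    cache <<- list(design = design, cohort = cohort, split = split,
                   arch = arch, config = config, model = model,
                   holdout_expr = holdout_expr, holdout_pred = holdout_pred)
    cache
  }
})
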