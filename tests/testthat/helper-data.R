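# Shared synthetic fixtures, generated once per test run and memoized
# so heavier checks (ranking, IFS, repeated CV) reuse the same data.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Study-condition defaults: 3 x 100 cells, 2000 genes, 20 markers/class,
# effect 2.0, dropout 0.3, seed 7.
default_dataset <- function() memo("default_ds", generate_dataset(generator_config()))

default_ranking <- function(k = 100) {
  memo(paste0("default_rank_", k), {
    ds <- default_dataset()
    fz <- remove_all_zero_features(ds$matrix)
    disc <- discretize_three_state(fz$filtered)
    list(ranking = mrmr_rank(disc, ds$labels, k = k),
         filtered = fz$filtered)
  })
}

null_dataset <- function()
  memo("null_ds", generate_dataset(generator_config(effect_size = 0)))

# Small planted dataset for quick structural checks.
small_dataset <- function(seed = 7)
  memo(paste0("small_ds_", seed),
       generate_dataset(generator_config(
         n_per_class = c(40L, 40L, 40L), n_genes = 120L,
         markers_per_class = 8L, seed = seed)))

# Single-feature threshold-separable two-class data with a margin.
separable_dataset <- function() {
  x <- matrix(c(seq(0.5, 4, length.out = 8),
                seq(6, 12, length.out = 14)),
              ncol = 1, dimnames = list(NULL, "marker"))
  list(x = x, y = c(rep("A", 8), rep("B", 14)))
}
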