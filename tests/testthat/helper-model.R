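# Shared objects for the suite. Model-curve evaluations are memoised inside
# the package, so building these once keeps the whole run fast.

default_grid <- sampling_grid()
default_cfg <- model_config()

# Small grid for randomized-stimulus property tests (not the study
# conditions; properties hold on any valid grid).
small_grid <- sampling_grid(x_extent = 4, t_extent = 0.8)
small_cfg <- model_config(grid = small_grid)

# Replace the sample values of a stimulus, keeping grid/spec metadata.
with_values <- function(stim, values) {
  stim$values <- values
  stim
}

# Long-format fitted-k table reshaped to photopic/scotopic pairs.
paired_k <- function(fits, which_task) {
  f <- fits[fits$task == which_task, ]
  k_col <- if ("k_best" %in% names(f)) "k_best" else "k"
  ph <- f[f$condition == "photopic", ]
  sc <- f[f$condition == "scotopic", ]
  ph <- ph[order(ph$observer), ]
  sc <- sc[order(sc$observer), ]
  stopifnot(identical(ph$observer, sc$observer))
  list(photopic = ph[[k_col]], scotopic = sc[[k_col]])
}
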