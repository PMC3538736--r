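# Small phantoms keep the unit tests fast; acceptance tests use the full
# 128x128 grid.
small_spec <- function(..., grid_shape = c(48L, 48L)) {
  phantom_spec(grid_shape = grid_shape, ...)
}

# Frame noise sd giving a target relative noise level on the averaged
# tag/control difference image: sd(dM_hat) = sigma * sqrt(2 / n_pairs).
noise_sigma_for_dm_fraction <- function(frac, f = 416, m0 = 100, n_pairs = 30) {
  frac * fair_forward_delta_m(f, m0) * sqrt(n_pairs / 2)
}

# Independent rectangle-rule convolution oracle (plain double loop).
conv_oracle <- function(ca, r, dt) {
  n <- length(ca)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) acc <- acc + ca[j] * r[i - j + 1]
    out[i] <- dt * acc
  }
  out
}

max_rel_err <- function(est, truth) {
  max(abs(est - truth) / pmax(abs(truth), 1))
}
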