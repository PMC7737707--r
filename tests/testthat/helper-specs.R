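# Shared fixture builders; everything is generated in code at test time.

# Uncorrelated unit-variance feature population with one effect attribute.
diag_spec <- function(p = 8, dm = 1, s = 2, shift = 2, effect = 1) {
  feature_sim_spec(attribute_names = paste0("attr", seq_len(p)),
                   control_mean = rep(0, p),
                   loadings = matrix(0, p, 0), noise_var = rep(1, p),
                   effect_attributes = effect, max_shift = shift,
                   dm_true = dm, s_true = s)
}

# Random full-rank correlated population (for oracle-equivalence checks).
rand_spec <- function(p = 8, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(p * 2, sd = 0.6), p, 2)
  feature_sim_spec(attribute_names = paste0("attr", seq_len(p)),
                   control_mean = rnorm(p, sd = 3),
                   loadings = L, noise_var = runif(p, 0.5, 2),
                   effect_attributes = 1, max_shift = 2,
                   dm_true = 1, s_true = 2)
}

# Flat-background field with one disk cell and optional painted fibers.
disk_cell_field <- function(radius = 40, center = c(64, 64), size = 128,
                            bg = 100, body = 350) {
  ch <- matrix(bg, size, size)
  mask <- matrix(0L, size, size)
  px <- phenoscreen:::ellipse_pixels(center[1], center[2], radius, radius,
                                     0, size, size)
  mask[px] <- 1L
  ch[px] <- body
  list(channel = ch, mask = mask, pixels = px)
}

# Noiseless Loewe / Bliss surfaces on a fold-spaced ladder.
combo_fixture <- function(model = c("bliss", "loewe"), Dm1 = 1, s1 = 1.2,
                          Dm2 = 0.8, s2 = 2, n_levels = 5, fold = 2,
                          top = 4) {
  model <- match.arg(model)
  d1 <- sort(top * fold^-(seq_len(n_levels) - 1))
  d2 <- d1
  f <- if (model == "bliss")
    outer(d1, d2, function(a, b) bliss_predict(a, b, Dm1, s1, Dm2, s2))
  else
    outer(d1, d2, function(a, b) loewe_predict(a, b, Dm1, s1, Dm2, s2))
  combination_matrix(
    d1, d2, f,
    edge_scores_1 = data.frame(dose = d1,
                               score = fractional_effect(d1, Dm1, s1)),
    edge_scores_2 = data.frame(dose = d2,
                               score = fractional_effect(d2, Dm2, s2)))
}
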