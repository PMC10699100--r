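# Shared fixtures: a small fast config and stock antibody sets.

small_config <- function(...) {
  simulation_config(width = 256L, height = 256L, n_cells = 10L,
                    ring_radius_range = c(12, 20), ...)
}

stock_antibodies <- function(rhos = c(ref = 1, mid = 0.6, lowab = 0.1)) {
  abs <- lapply(names(rhos), function(id) antibody_model(id, rhos[[id]]))
  c(abs, list(antibody_model("ctrl", 0, is_control = TRUE)))
}

# Independent closed-form OLS oracle (never calls the fitting code under test).
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Independent naive double-loop region mean.
naive_region_mean <- function(mat, x0, y0, size) {
  total <- 0
  for (dy in seq_len(size))
    for (dx in seq_len(size))
      total <- total + mat[y0 + dy, x0 + dx]
  total / (size * size)
}
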