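# Small shared fixtures built in code.

small_grid <- function(n = 65) make_grid(3.3, n)

# grid whose samples land exactly on integer-multiple radii of 0.03 mm
exact_grid <- function() make_grid(3.3, 221)

# uniform PRP map over a 6-mm zone
uniform_prp <- function(value, n = 65, spacing = 6.6 / (n - 1)) {
  as_prp_map(matrix(value, n, n), spacing)
}

# central red disc of given radius inside a uniform background
disc_prp <- function(centre_value, bg_value, radius, n = 201,
                     spacing = 6.6 / (n - 1)) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  r <- sqrt(outer(ax^2, ax^2, "+"))
  m <- matrix(bg_value, n, n)
  m[r <= radius] <- centre_value
  as_prp_map(m, spacing)
}

# matrix rotated by 90 degrees (exact resampling on a square grid)
rot90 <- function(m) t(m[nrow(m):1, ])

# a mildly perturbed control-like cornea on a small grid, deterministic
test_cornea <- function(seed = 7, n = 65) {
  cfg <- cohort_config(
    list(g = list(preset = ek_presets$control, n = 1, timepoints = "pre")),
    grid = small_grid(n)
  )
  eye_cornea(sample_cohort(cfg, seed = seed), 1)
}
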