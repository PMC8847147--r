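# Shared fixtures, built in code.

# tiny deterministic census for two plants, one year, 4-day visits
toy_census <- function() {
  data.frame(
    individual_id = rep(c("a", "b"), each = 4),
    year = "y1",
    day = rep(c(108, 112, 116, 120), 2),
    leaflets_total = rep(c(10L, 8L), each = 4),
    leaflets_unfolded = c(0L, 0L, 3L, 6L, 0L, 0L, 1L, 4L),
    bud_size = c(0, 0, 2.5, 6.0, 0, 0, 1.0, 4.5),
    flowers_open = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L),
    grazed = FALSE,
    stringsAsFactors = FALSE
  )
}

# analysis frame with a known linear surface and Gaussian fitness noise,
# independent of the package's generator (used as a cross-check)
toy_selection_frame <- function(n, beta_L = 0, beta_F = 0, beta_size = 0,
                                rho = 0, sd_noise = 0.3, seed = 1) {
  set.seed(seed)
  zL <- rnorm(n)
  zF <- rho * zL + sqrt(1 - rho^2) * rnorm(n)
  zS <- rnorm(n)
  w <- pmax(0, 1 + beta_L * zL + beta_F * zF + beta_size * zS + rnorm(n, 0, sd_noise))
  data.frame(
    individual_id = sprintf("i%05d", seq_len(n)), year = "y1",
    leaf_out_day = 110 + 6 * zL,
    first_flowering_day = 126 + 7 * zF,
    development_time = (126 + 7 * zF) - (110 + 6 * zL),
    aboveground_volume = exp(6 + 0.8 * zS),
    fitness_intact_seeds = w,
    stringsAsFactors = FALSE
  )
}

# independent normal-equations OLS oracle: solve (X'X) b = X'y directly
ols_oracle <- function(X, y) unname(drop(solve(crossprod(X), crossprod(X, y))))
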