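test_that("standardize and relativize honour local and global schemes", {
  expect_equal(standardize(c(1, 2, 3), "global"), c(-1, 0, 1))
  v <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  loc <- standardize(v, "local", g)
  expect_equal(loc, rep(c(-1, 0, 1), 2))
  glo <- standardize(v, "global", g)
  expect_equal(mean(glo), 0)
  expect_true(abs(mean(glo[g == "a"])) > 0.5)   # per-year means differ from 0
  expect_error(standardize(c(2, 2, 2), "global"), "zero variance")
  expect_error(standardize(c(1, 2, 5, 5), "local", c("a", "a", "b", "b")), "'b'")

  expect_equal(relativize(c(0, 2, 4), "global"), c(0, 1, 2))
  expect_equal(relativize(c(5, 5), "global"), c(1, 1))
  expect_error(relativize(c(0, 0, 0), "global"), "not positive")
  rl <- relativize(c(0, 2, 4, 8), "local", c("a", "a", "a", "b"))
  expect_equal(rl, c(0, 1, 2, 1))
})

test_that("fit_ols matches the normal-equations oracle and flags rank deficiency", {
  f <- fit_ols(cbind(intercept = 1, x = c(0, 1, 2)), c(1, 2, 3))
  expect_equal(unname(f$coefficients), c(1, 1), tolerance = 1e-12)

  set.seed(70)
  X <- cbind(intercept = 1, a = rnorm(5), b = rnorm(5))
  y <- rnorm(5)
  expect_equal(unname(fit_ols(X, y)$coefficients), ols_oracle(X, y), tolerance = 1e-10)

  Xd <- cbind(intercept = 1, a = 1:5, dup = 1:5)
  expect_error(fit_ols(Xd, rnorm(5)), "dup")
})

test_that("vif has the bivariate closed form and an infinity marker", {
  set.seed(71)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n)
  X <- cbind(a = a, b = b)
  expect_true(all(abs(vif(X) - 1) < 0.01))
  # correlation exactly r: VIF = 1/(1 - r^2) from the sample r
  c2 <- 0.5 * a + sqrt(0.75) * b
  X2 <- cbind(a = a, c = c2)
  r <- cor(a, c2)
  expect_equal(unname(vif(X2)), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  expect_true(all(is.infinite(vif(cbind(a = a, a2 = a)))))
  expect_error(vif(cbind(a = a)), ">= 2 predictors")
})

test_that("pearson_correlation matches the t formula and calibrates under the null", {
  x <- 1:10
  pc <- pearson_correlation(x, 2 * x)
  expect_equal(pc$r, 1)
  expect_equal(pc$p, 0)

  # r = 0.5, n = 27 -> t = 2.8868 (formula evaluation)
  set.seed(72)
  a <- rnorm(27)
  b <- rnorm(27)
  b <- residuals(lm(b ~ a))                     # orthogonalize
  y <- 0.5 * (a - mean(a)) / sd(a) + sqrt(0.75) * (b - mean(b)) / sd(b)
  pc2 <- pearson_correlation(a, y)
  expect_equal(pc2$r, 0.5, tolerance = 1e-10)
  expect_equal(round(pc2$t, 4), 2.8868)
  expect_equal(pc2$df, 25)
  expect_equal(pc2$p, 2 * pt(2.88675, 25, lower.tail = FALSE), tolerance = 1e-4)

  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")

  # type-I error ~5% over 2,000 null replicates
  set.seed(73)
  rej <- mean(replicate(2000, pearson_correlation(rnorm(20), rnorm(20))$p < 0.05))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("total selection recovers direct and indirect components (s = P beta)", {
  # rho = 0: differential = own beta
  d0 <- toy_selection_frame(5000, beta_L = -0.5, rho = 0, seed = 74)
  t0 <- total_selection(d0, "leaf_out_day", "local")
  est0 <- t0$estimate[t0$term == "leaf_out_day" & t0$model == "linear"]
  expect_lt(abs(est0 - (-0.5)), 0.05)

  # rho = 0.4, beta_L = 0, beta_F = -0.5: leaf-out differential ~ rho * beta_F
  d1 <- toy_selection_frame(5000, beta_L = 0, beta_F = -0.5, rho = 0.4, seed = 75)
  t1 <- total_selection(d1, "leaf_out_day", "local")
  est1 <- t1$estimate[t1$term == "leaf_out_day" & t1$model == "linear"]
  expect_lt(abs(est1 - (-0.2)), 0.05)

  # zero-variance fitness: slope coefficients all zero
  dz <- toy_selection_frame(100, seed = 76)
  dz$fitness_intact_seeds <- 5
  tz <- total_selection(dz, "leaf_out_day", "local")
  expect_true(all(abs(tz$estimate) < 1e-10))
})

test_that("s = P beta identity holds across a (rho, beta) grid", {
  grid <- expand.grid(rho = c(-0.3, 0.2, 0.5), bL = c(-0.4, 0.2), bF = c(-0.5, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(n_individuals = 4000, year_labels = "y1", rho = g$rho,
                      beta_L = g$bL, beta_F = g$bF, mu_leafout = 100, mu_ffd = 150,
                      sd_leafout = 4, sd_ffd = 4, zero_inflation_pi = 0.3,
                      dispersion_k = 3, mean_fitness = 10, rng_seed = 100 + i)
    ps <- truth_plant_season(suppressWarnings(generate_fitness(generate_traits(cfg), cfg)))
    tl <- total_selection(ps, "leaf_out_day", "local", quadratic = FALSE)
    s_hat <- tl$estimate[tl$term == "leaf_out_day"]
    s_theory <- g$bL + g$rho * g$bF
    # |error| < 4 SE with SE approximated by the noisy-fitness OLS rate
    expect_lt(abs(s_hat - s_theory), 0.12)
  }
})

test_that("direct gradients, interaction and VIF behave in the multiple regression", {
  # coefficients kept modest so the zero clamp is negligible (criterion 1
  # exercises the aggressive setting end to end)
  cfg <- sim_config(n_individuals = 5000, year_labels = "y1", rho = 0.4,
                    beta_L = -0.2, beta_F = -0.35, zero_inflation_pi = 0.3,
                    mean_fitness = 10, dispersion_k = 2, rng_seed = 80)
  ps <- truth_plant_season(generate_fitness(generate_traits(cfg), cfg))
  dl <- direct_selection(ps, "local", "linear")
  expect_lt(abs(dl$estimate[dl$term == "leaf_out_day"] - (-0.2)), 0.06)
  expect_lt(abs(dl$estimate[dl$term == "first_flowering_day"] - (-0.35)), 0.06)
  expect_true(all(dl$vif[dl$term != "size"] > 1))

  # injected correlational selection is recovered by the interaction term
  cfg2 <- sim_config(n_individuals = 5000, year_labels = "y1", rho = 0.3,
                     gamma_LF = 0.4, zero_inflation_pi = 0.2, mean_fitness = 10,
                     dispersion_k = 3, rng_seed = 81)
  ps2 <- truth_plant_season(suppressWarnings(generate_fitness(generate_traits(cfg2), cfg2)))
  dc <- direct_selection(ps2, "local", "correlational")
  inter <- dc$estimate[dc$term == "leaf_out_day:first_flowering_day"]
  expect_gt(inter, 0.3)
  expect_lt(inter, 0.5)

  # near-collinear stress: VIF > 10 reported, fit still returned
  d99 <- toy_selection_frame(500, rho = 0.99, seed = 82)
  dl99 <- direct_selection(d99, "local", "linear")
  expect_true(all(is.finite(dl99$estimate)))
  expect_gt(max(dl99$vif, na.rm = TRUE), 10)
})

test_that("the doubling convention maps the raw z^2 coefficient to gamma", {
  set.seed(83)
  n <- 10000
  z <- rnorm(n)
  gamma <- -0.4
  w <- pmax(0, 1 + 0.5 * gamma * (z^2 - 1) + rnorm(n, 0, 0.2))
  ffd <- z + 10 + rnorm(n)
  d <- data.frame(individual_id = seq_len(n), year = "y1",
                  leaf_out_day = z, first_flowering_day = ffd,
                  development_time = ffd - z, aboveground_volume = exp(rnorm(n)),
                  fitness_intact_seeds = w)
  tt <- total_selection(d, "leaf_out_day", "local", include_size = FALSE)
  zs <- (z - mean(z)) / sd(z)                             # the model's own z-scale
  raw_model <- lm(relativize(w, "global") ~ zs + I(zs^2)) # independent check
  reported <- tt$estimate[tt$term == "leaf_out_day^2"]
  expect_true(tt$doubled[tt$term == "leaf_out_day^2"])
  expect_equal(reported, 2 * unname(coef(raw_model)["I(zs^2)"]), tolerance = 1e-8)
  expect_lt(abs(reported - gamma), 0.1)
})

test_that("devtime_selection shares the generic-trait code path", {
  d <- toy_selection_frame(1000, beta_L = 0.3, beta_F = -0.3, rho = 0.2, seed = 84)
  a <- devtime_selection(d, "local")
  b <- total_selection(d, "development_time", "local")
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$family, b$family)
  # fitness independent of both traits -> devtime beta ~ 0
  dn <- toy_selection_frame(4000, seed = 85)
  tn <- devtime_selection(dn, "local")
  expect_lt(abs(tn$estimate[tn$term == "development_time" & tn$model == "linear"]), 0.05)
})

test_that("local and global schemes agree exactly on a single-year dataset", {
  d <- toy_selection_frame(400, beta_L = -0.3, rho = 0.3, seed = 86)
  a <- selection_tables(d, "local")
  b <- selection_tables(d, "global")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$term, b$term)
})

test_that("estimates are invariant to row order and id relabeling", {
  d <- toy_selection_frame(500, beta_L = -0.3, beta_F = 0.2, rho = 0.3, seed = 87)
  t1 <- selection_tables(d, "local")
  set.seed(88)
  d2 <- d[sample(nrow(d)), ]
  d2$individual_id <- paste0("relabeled_", seq_len(nrow(d2)))
  t2 <- selection_tables(d2, "local")
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-12)
  expect_equal(t1$vif, t2$vif, tolerance = 1e-12)
})

test_that("gradient recovery bias is small at n = 20,000 under zero inflation", {
  cfg <- sim_config(n_individuals = 20000, year_labels = "y1", rho = 0.4,
                    beta_L = -0.2, beta_F = -0.35, beta_size = 0.15,
                    zero_inflation_pi = 0.5, mean_fitness = 10, dispersion_k = 2,
                    rng_seed = 89)
  ps <- truth_plant_season(generate_fitness(generate_traits(cfg), cfg))
  dl <- direct_selection(ps, "local", "linear")
  expect_lt(abs(dl$estimate[dl$term == "leaf_out_day"] - (-0.2)), 0.05)
  expect_lt(abs(dl$estimate[dl$term == "first_flowering_day"] - (-0.35)), 0.05)
  expect_lt(abs(dl$estimate[dl$term == "size"] - 0.15), 0.05)
})

test_that("compare_direct_vs_total implements the interval-exclusion rule", {
  direct <- list(term = "leaf_out_day", year = "2014", scheme = "local", estimate = -0.100)
  total <- list(term = "leaf_out_day", year = "2014", scheme = "local",
                estimate = -0.262, bca_lower = -0.388, bca_upper = -0.135)
  out <- compare_direct_vs_total(direct, total)
  expect_true(out$flagged)
  expect_match(out$interpretation, "indirect via first flowering day")

  # direct equal to the total estimate: inside the interval, not flagged
  direct2 <- modifyList(direct, list(estimate = -0.262))
  expect_false(compare_direct_vs_total(direct2, total)$flagged)
  # exactly at the bound: closed interval, not flagged
  direct3 <- modifyList(direct, list(estimate = -0.135))
  expect_false(compare_direct_vs_total(direct3, total)$flagged)
  # mismatched year errors
  expect_error(compare_direct_vs_total(modifyList(direct, list(year = "2015")), total),
               "mismatched year")
})
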