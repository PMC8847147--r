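test_that("fit_unfolding_model matches exact and normal-equation oracles", {
  # exact fit: unfolded = 0.5 * total
  tot <- c(4, 6, 8, 10, 12)
  m <- fit_unfolding_model(tot, 0.5 * tot)
  expect_equal(unname(m$coefficients), c(0, 0.5, 0), tolerance = 1e-10)

  # 4-point toy set vs the normal equations solved directly
  tot2 <- c(4, 6, 8, 10); unf <- c(1, 3, 4, 7)
  m2 <- fit_unfolding_model(tot2, unf)
  X <- cbind(1, tot2, tot2^2)
  expect_equal(unname(m2$coefficients), ols_oracle(X, unf), tolerance = 1e-10)
  expect_equal(predict_unfolded(m2, 6), drop(c(1, 6, 36) %*% ols_oracle(X, unf)),
               tolerance = 1e-10)

  expect_error(fit_unfolding_model(c(4, 4, 8, 8), c(1, 2, 3, 4)), "3 distinct")
})

test_that("assign_leaf_out_day maps deviation percentiles into the interval", {
  tot <- c(4, 6, 8, 10, 12)
  m <- fit_unfolding_model(tot, 0.5 * tot)

  # interval of length 1: the only candidate day (up to percentile placement
  # within that day) and always inside (prev, first]
  d1 <- assign_leaf_out_day(119, 120, 3, 6, m)
  expect_gt(d1, 119)
  expect_lte(d1, 120)

  # single plant = median percentile (p = 0.5): midpoint of a 4-day interval
  expect_equal(assign_leaf_out_day(116, 120, 3, 6, m), 118.0)

  # larger deviation -> earlier day, same interval
  two <- assign_leaf_out_day(c(116, 116), c(120, 120),
                             observed_unfolded = c(5, 2), leaflets_total = c(6, 6), m)
  expect_lt(two[1], two[2])

  expect_error(assign_leaf_out_day(120, 116, 3, 6, m), "must not exceed")
  expect_error(assign_leaf_out_day(116, 120, 3, 6, model = NULL), "model")
})

test_that("deviation ties are broken by id order, deterministically", {
  tot <- c(4, 6, 8, 10, 12)
  m <- fit_unfolding_model(tot, 0.5 * tot)
  days <- assign_leaf_out_day(rep(116, 3), rep(120, 3), c(3, 3, 3), c(6, 6, 6), m,
                              ids = c("b", "a", "c"))
  expect_equal(order(days), order(c("b", "a", "c"), decreasing = TRUE))
  expect_identical(days,
                   assign_leaf_out_day(rep(116, 3), rep(120, 3), c(3, 3, 3), c(6, 6, 6), m,
                                       ids = c("b", "a", "c")))
})

test_that("assign_ffd_from_bud is monotone in bud size with midpoint fallback", {
  res <- assign_ffd_from_bud(c(6, 2, NA), c(130, 130, 130), c(134, 134, 134))
  expect_lt(res$day[1], res$day[2])          # bigger bud -> earlier
  expect_equal(res$day[3], 132)              # midpoint fallback
  expect_identical(res$midpoint_fallback, c(FALSE, FALSE, TRUE))
  # extreme bud percentile is earliest but still > prev day
  n <- 50
  r <- assign_ffd_from_bud(seq_len(n), rep(130, n), rep(134, n))
  expect_equal(which.min(r$day), n)
  expect_gt(min(r$day), 130)
  expect_lte(max(r$day), 134)
})

test_that("bud-size monotonicity holds across simulated plants sharing an interval", {
  cfg <- sim_config(n_individuals = 100, year_labels = "y1", rng_seed = 21)
  sim <- simulate_dataset(cfg)
  ps <- estimate_phenology(sim$census)
  cs <- sim$census
  # group plants by their bracketing flowering interval and check rank inversion
  firsts <- do.call(rbind, lapply(split(cs, cs$individual_id), function(v) {
    j <- which(v$flowers_open >= 1)[1]
    if (is.na(j) || j == 1) return(NULL)
    data.frame(individual_id = v$individual_id[1], first = v$day[j],
               bud = v$bud_size[j - 1])
  }))
  merged <- merge(firsts, ps[, c("individual_id", "first_flowering_day")])
  for (iv in split(merged, merged$first)) {
    iv <- iv[!duplicated(iv$bud), ]      # ties are broken by id, not bud rank
    if (nrow(iv) >= 2) {
      expect_true(all(diff(iv$first_flowering_day[order(iv$bud)]) < 0))
    }
  }
})

test_that("grazed-plant flowering model matches the normal-equation oracle", {
  set.seed(31)
  n <- 25
  bud <- runif(n, 1, 8); day <- runif(n, 120, 140); vol <- exp(rnorm(n, 6, 0.5))
  ffd <- 100 + 1.5 * bud + 0.2 * day - 2 * log(vol) + rnorm(n, 0, 0.5)
  m <- fit_grazed_ffd_model(ffd, bud, day, vol)
  b <- ols_oracle(cbind(1, bud, day, log(vol)), ffd)
  expect_equal(unname(m$coefficients), b, tolerance = 1e-10)
  # grazed plant identical in predictors to a training row -> its fitted value
  expect_equal(estimate_ffd_grazed(bud[1], day[1], vol[1], m),
               drop(c(1, bud[1], day[1], log(vol[1])) %*% b), tolerance = 1e-10)
  expect_message(out <- estimate_ffd_grazed(c(bud[1], NA), c(day[1], 130), c(vol[1], 400), m),
                 "excluded")
  expect_true(is.na(out[2]))
  expect_error(fit_grazed_ffd_model(numeric(0), numeric(0), numeric(0), numeric(0)),
               "no intact plants")
})

test_that("aboveground_volume evaluates the cylinder formula exactly", {
  expect_equal(aboveground_volume(0, 7, 2), 0)
  expect_equal(aboveground_volume(2, 1, 1), pi)
  expect_equal(aboveground_volume(2, 10, 3), 30 * pi)  # 94.2478
  expect_equal(round(aboveground_volume(2, 10, 3), 4), 94.2478)
  expect_error(aboveground_volume(-1, 2, 1), ">= 0")
})

test_that("impute_grazed_height uses the model or the max spring height", {
  m <- fit_height_diameter_model(height = c(5, 10, 15, 20), diameter = c(1, 2, 3, 4))
  expect_equal(impute_grazed_height(4, m), 20, tolerance = 1e-10)
  set.seed(32)
  d <- runif(20, 1, 5); h <- 3 + 4.2 * d + rnorm(20, 0, 0.3)
  m2 <- fit_height_diameter_model(h, d)
  expect_equal(unname(m2$coefficients), ols_oracle(cbind(1, d), h), tolerance = 1e-10)
  expect_equal(impute_grazed_height(c(2, 3), m2, use_max_spring = c(FALSE, TRUE),
                                    max_spring_height = c(NA, 27))[2], 27)
  expect_error(fit_height_diameter_model(numeric(0), numeric(0)), "no nongrazed")
})

test_that("estimate_phenology brackets every assigned day and flags boundary cases", {
  cfg <- sim_config(n_individuals = 300, year_labels = "y1", visit_interval_days = 4,
                    rng_seed = 22)
  sim <- simulate_dataset(cfg)
  ps <- estimate_phenology(sim$census, sim$shoots)
  truth <- sim$truth[match(paste(ps$individual_id, ps$year),
                           paste(sim$truth$individual_id, sim$truth$year)), ]
  ok <- ps$leaf_out_flag == "ok"
  expect_gt(mean(ok), 0.9)
  # assigned day inside the true bracketing 4-day interval for 100% of plants
  err <- ps$leaf_out_day[ok] - truth$leaf_out_day[ok]
  expect_true(all(err > -4 & err < 4))
  # development-time identity holds exactly
  expect_equal(ps$development_time, ps$first_flowering_day - ps$leaf_out_day)
  # volume merged from shoots reproduces the generator's ln_size
  expect_equal(log(ps$aboveground_volume), truth$ln_size, tolerance = 1e-8)

  # plant whose leaf-out falls after the last visit is flagged, not assigned
  cs <- toy_census()
  cs$leaflets_unfolded[cs$individual_id == "b"] <- 0L
  cs$flowers_open[cs$individual_id == "b"] <- 0L
  ps2 <- estimate_phenology(cs)
  expect_true(is.na(ps2$leaf_out_day[ps2$individual_id == "b"]))
  expect_equal(ps2$leaf_out_flag[ps2$individual_id == "b"], "never_unfolded")
})

test_that("denser censusing reduces leaf-out error (MAE 1-day < 4-day)", {
  mae <- sapply(c(1, 4), function(iv) {
    cfg <- sim_config(n_individuals = 1000, year_labels = "y1",
                      visit_interval_days = iv, rng_seed = 23)
    sim <- simulate_dataset(cfg)
    ps <- estimate_phenology(sim$census)
    truth <- sim$truth[match(paste(ps$individual_id, ps$year),
                             paste(sim$truth$individual_id, sim$truth$year)), ]
    ok <- ps$leaf_out_flag == "ok"
    mean(abs(ps$leaf_out_day - truth$leaf_out_day)[ok])
  })
  expect_lt(mae[1], mae[2])
  # daily censusing removes (almost all) censoring: error within ~half a day
  expect_lt(mae[1], 0.75)
})
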