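#' Generate true phenology traits with a known correlation structure
#'
#' Samples, per year, (leaf-out day, first flowering day) from a bivariate
#' normal with correlation `rho` and ln aboveground volume from an independent
#' normal. Individuals whose sampled first flowering day falls before leaf-out
#' are resampled (not truncated) so the marginals are preserved; the number of
#' resampled individuals is recorded in `attr(x, "n_resampled")`. More than
#' 1,000 retries for a single slot is an error.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `individual_id`, `year`, `leaf_out_day`,
#'   `ffd`, `ln_size` (one row per individual x year).
#' @export
generate_traits <- function(config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "traits"))
  n <- config$n_individuals
  res <- list()
  n_resampled <- 0L
  for (yr in config$year_labels) {
    zz <- rbvn(n, config$rho)
    lo <- config$mu_leafout + config$sd_leafout * zz[, 1]
    ff <- config$mu_ffd + config$sd_ffd * zz[, 2]
    bad <- which(ff < lo)
    for (i in bad) {
      tries <- 0L
      repeat {
        z2 <- rbvn(1L, config$rho)
        lo[i] <- config$mu_leafout + config$sd_leafout * z2[, 1]
        ff[i] <- config$mu_ffd + config$sd_ffd * z2[, 2]
        tries <- tries + 1L
        if (ff[i] >= lo[i]) break
        if (tries >= 1000L) {
          stop("generate_traits: could not sample ffd >= leaf_out after 1000 retries; ",
               "check mu_ffd - mu_leafout relative to the trait SDs", call. = FALSE)
        }
      }
      n_resampled <- n_resampled + 1L
    }
    res[[yr]] <- data.frame(
      individual_id = sprintf("ind_%04d", seq_len(n)),
      year = yr,
      leaf_out_day = lo,
      ffd = ff,
      ln_size = stats::rnorm(n, config$mu_lnsize, config$sd_lnsize),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_resampled") <- n_resampled
  out
}

# bivariate standard normal via Cholesky; returns n x 2 matrix
rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Generate seed counts from the configured selection surface
#'
#' Traits are standardized to z-scores within year, the expected
#' relative-fitness surface (see [sim_config()]) is evaluated and clamped at
#' zero, and realized seed counts are drawn from a zero-inflated negative
#' binomial with mean `mean_fitness * w` and shape `dispersion_k`.
#' Zero inflation is trait-independent by default, so the relative-fitness
#' surface is preserved in expectation and the configured coefficients remain
#' recoverable downstream. A trait-dependent option (`pi_slope_F`) exists for
#' sensitivity work but is excluded from validation.
#'
#' @param traits output of [generate_traits()].
#' @param config a [sim_config()].
#' @param pi_slope_F optional logit-scale dependence of the zero-inflation
#'   probability on the flowering z-score (default 0 = trait-independent).
#' @return `traits` with columns `w_true` (expected relative fitness) and
#'   `seeds` (realized count) appended. Warns when the zero clamp affects
#'   more than 5% of individuals.
#' @export
generate_fitness <- function(traits, config, pi_slope_F = 0) {
  validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "fitness"))
  zL <- zF <- zS <- numeric(nrow(traits))
  for (yr in unique(traits$year)) {
    i <- traits$year == yr
    zL[i] <- zscore(traits$leaf_out_day[i])
    zF[i] <- zscore(traits$ffd[i])
    zS[i] <- zscore(traits$ln_size[i])
  }
  w <- 1 + config$beta_L * zL + config$beta_F * zF + config$beta_size * zS +
    0.5 * config$gamma_LL * (zL^2 - 1) + 0.5 * config$gamma_FF * (zF^2 - 1) +
    config$gamma_LF * (zL * zF - config$rho)
  clamped <- w < 0
  if (mean(clamped) > 0.5) {
    warning("generate_fitness: selection surface negative for >50% of individuals; ",
            "coefficients will not be recoverable", call. = FALSE)
  } else if (mean(clamped) > 0.05) {
    warning(sprintf("generate_fitness: fitness surface clamped at 0 for %.1f%% of individuals",
                    100 * mean(clamped)), call. = FALSE)
  }
  w[clamped] <- 0
  mu <- config$mean_fitness * w
  seeds <- stats::rnbinom(length(mu), size = config$dispersion_k, mu = mu)
  pi0 <- stats::plogis(stats::qlogis(pmin(pmax(config$zero_inflation_pi, 1e-12), 1 - 1e-12)) +
                         pi_slope_F * zF)
  if (config$zero_inflation_pi == 0 && pi_slope_F == 0) pi0 <- 0
  seeds[stats::runif(length(seeds)) < pi0] <- 0L
  traits$w_true <- w
  traits$seeds <- as.integer(seeds)
  traits
}

zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate an interval-censored census from true phenology
#'
#' Emits one row per individual x visit on a shared schedule (every
#' `visit_interval_days` days spanning the season). Leaflets unfold
#' sequentially from the true leaf-out day over a per-individual unfolding
#' duration; the largest bud grows linearly up to the true first flowering
#' day; `flowers_open` becomes positive from the true flowering day. True
#' event days are carried in `true_leaf_out` / `true_ffd` columns for
#' validation only — a field dataset would not have them.
#'
#' @param traits output of [generate_traits()].
#' @param config a [sim_config()].
#' @return data.frame of census records: `individual_id`, `year`, `day`,
#'   `leaflets_total`, `leaflets_unfolded`, `bud_size`, `flowers_open`,
#'   `grazed`, `true_leaf_out`, `true_ffd`.
#' @export
generate_census <- function(traits, config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "census"))
  out <- vector("list", length(unique(traits$year)))
  names(out) <- unique(traits$year)
  for (yr in unique(traits$year)) {
    tr <- traits[traits$year == yr, ]
    n <- nrow(tr)
    first_day <- floor(min(tr$leaf_out_day)) - config$visit_interval_days
    last_day <- ceiling(max(tr$ffd)) + config$visit_interval_days
    days <- seq(first_day, last_day, by = config$visit_interval_days)
    total <- sample(seq(config$leaflet_count_range[1], config$leaflet_count_range[2]),
                    n, replace = TRUE)
    unfold_dur <- stats::runif(n, config$unfolding_days_range[1], config$unfolding_days_range[2])
    bud_growth <- stats::runif(n, 0.5, 1.1)   # mm/day
    bud_max <- stats::runif(n, 6, 10)         # mm at flowering
    grid <- expand.grid(i = seq_len(n), day = days)
    lo <- tr$leaf_out_day[grid$i]
    ff <- tr$ffd[grid$i]
    tot <- total[grid$i]
    prog <- (grid$day - lo) / unfold_dur[grid$i]
    unfolded <- ifelse(grid$day < lo, 0L, pmin(tot, 1L + floor(prog * (tot - 1L))))
    bud <- pmax(0, bud_max[grid$i] - bud_growth[grid$i] * (ff - grid$day))
    bud[grid$day >= ff] <- bud_max[grid$i][grid$day >= ff]
    flowers <- ifelse(grid$day < ff, 0L, pmin(9L, 1L + floor((grid$day - ff) / 2)))
    out[[yr]] <- data.frame(
      individual_id = tr$individual_id[grid$i],
      year = yr,
      day = grid$day,
      leaflets_total = tot,
      leaflets_unfolded = as.integer(unfolded),
      bud_size = round(bud, 2),
      flowers_open = as.integer(flowers),
      grazed = FALSE,
      true_leaf_out = lo,
      true_ffd = ff,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$year, res$individual_id, res$day), ]
  rownames(res) <- NULL
  res
}

#' Generate fruit records with a seed-predation layer
#'
#' Packs each individual's seed count into fruits of at most
#' `max_seeds_per_fruit` seeds. For closed pods each seed independently
#' receives Poisson(`holes_rate`) entry holes and `n_entry_holes` records how
#' many seeds were damaged (>= 1 hole); for opened pods only the total number
#' of wall holes, Poisson(`holes_rate` x seeds), is observable.
#'
#' @param fitness output of [generate_fitness()] (needs `individual_id`,
#'   `year`, `seeds`).
#' @param config a [sim_config()].
#' @return data.frame of fruit records: `individual_id`, `year`, `fruit_id`,
#'   `n_seeds`, `n_entry_holes`, `pod_opened`, `per_seed_holes_observed`.
#' @export
generate_fruits <- function(fitness, config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "fruits"))
  keep <- fitness$seeds > 0
  id <- fitness$individual_id[keep]
  yr <- fitness$year[keep]
  seeds <- fitness$seeds[keep]
  rows <- vector("list", length(seeds))
  for (j in seq_along(seeds)) {
    s <- seeds[j]
    per <- integer(0)
    while (s > 0) {
      take <- min(s, sample.int(config$max_seeds_per_fruit, 1))
      per <- c(per, take)
      s <- s - take
    }
    opened <- stats::runif(length(per)) < config$prop_pods_open
    holes <- integer(length(per))
    for (k in seq_along(per)) {
      if (opened[k]) {
        holes[k] <- stats::rpois(1, config$holes_rate * per[k])
      } else {
        holes[k] <- sum(stats::rpois(per[k], config$holes_rate) > 0)
      }
    }
    rows[[j]] <- data.frame(
      individual_id = id[j], year = yr[j],
      fruit_id = seq_along(per),
      n_seeds = per, n_entry_holes = holes,
      pod_opened = opened, per_seed_holes_observed = !opened,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(individual_id = character(0), year = character(0),
                      fruit_id = integer(0), n_seeds = integer(0),
                      n_entry_holes = integer(0), pod_opened = logical(0),
                      per_seed_holes_observed = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a shoot-size table consistent with the true ln volumes
#'
#' Decomposes each individual's true aboveground volume into shoot number,
#' diameter and height so that [aboveground_volume()] applied to the table
#' recovers `exp(ln_size)` exactly.
#'
#' @param traits output of [generate_traits()].
#' @param config a [sim_config()].
#' @return data.frame: `individual_id`, `year`, `shoot_height`,
#'   `shoot_diameter`, `n_shoots`, `grazed_spring`, `grazed_after_spring`,
#'   `max_spring_height`.
#' @export
generate_shoots <- function(traits, config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "shoots"))
  n <- nrow(traits)
  n_shoots <- 1L + stats::rpois(n, 1.0)
  diameter <- stats::rlnorm(n, meanlog = 1.1, sdlog = 0.2)  # mm
  vol <- exp(traits$ln_size)
  height <- vol / ((0.5 * diameter)^2 * pi * n_shoots)      # cm, closes the identity
  data.frame(
    individual_id = traits$individual_id, year = traits$year,
    shoot_height = height, shoot_diameter = diameter, n_shoots = n_shoots,
    grazed_spring = FALSE, grazed_after_spring = FALSE,
    max_spring_height = height,
    stringsAsFactors = FALSE
  )
}

#' Convert a truth table to an analysis-ready PlantSeason frame
#'
#' Bypasses the census/fruit observation layers: uses the true event days,
#' `exp(ln_size)` as aboveground volume, and the realized seed counts as
#' fitness. Useful for validating the selection engine in isolation from
#' phenology-estimation error.
#'
#' @param truth output of [generate_fitness()].
#' @return PlantSeason data.frame accepted by [prepare_selection_data()].
#' @export
truth_plant_season <- function(truth) {
  data.frame(
    individual_id = truth$individual_id, year = truth$year,
    leaf_out_day = truth$leaf_out_day,
    first_flowering_day = truth$ffd,
    development_time = truth$ffd - truth$leaf_out_day,
    aboveground_volume = exp(truth$ln_size),
    fitness_intact_seeds = truth$seeds,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete dataset (traits, fitness, census, fruits, shoots)
#'
#' @param config a [sim_config()].
#' @return list with elements `truth` (traits + expected/realized fitness),
#'   `census`, `fruits`, `shoots`, and `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- generate_fitness(generate_traits(config), config)
  list(
    truth = truth,
    census = generate_census(truth, config),
    fruits = generate_fruits(truth, config),
    shoots = generate_shoots(truth, config),
    config = config
  )
}

#' Write the simulated tables to CSV files
#'
#' All columns — including the hidden truth columns — round-trip unchanged
#' through [utils::write.csv()] / [utils::read.csv()] at full precision.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    truth = file.path(dir, "truth.csv"),
    census = file.path(dir, "census.csv"),
    fruits = file.path(dir, "fruits.csv"),
    shoots = file.path(dir, "shoots.csv"),
    config = file.path(dir, "sim_config.txt")
  )
  for (nm in c("truth", "census", "fruits", "shoots")) {
    utils::write.csv(format_full_precision(sim[[nm]]), paths[[nm]], row.names = FALSE, quote = TRUE)
  }
  write_sim_config(sim$config, paths[["config"]])
  invisible(paths)
}

# doubles written with 17 significant digits so read.csv round-trips exactly
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}
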