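#' Simulation configuration for the synthetic phenology dataset
#'
#' Bundles the ground-truth selection surface and the observation-process
#' parameters used by [generate_traits()], [generate_fitness()],
#' [generate_census()] and [generate_fruits()]. Defaults describe a perennial
#' understory herb censused every few days in spring: leaf-out around day 110
#' (late April), first flowering roughly two weeks later, moderate positive
#' correlation between the two dates, ln-normal plant size, and strongly
#' zero-inflated overdispersed seed counts.
#'
#' Selection coefficients are on the relative-fitness scale per standard
#' deviation of trait: expected relative fitness is
#' \deqn{w = 1 + \beta_L z_L + \beta_F z_F + \beta_{size} z_s +
#'   \tfrac12\gamma_{LL}(z_L^2 - 1) + \tfrac12\gamma_{FF}(z_F^2 - 1) +
#'   \gamma_{LF}(z_L z_F - \rho)}
#' clamped at zero. Quadratic and interaction regressors are centered so that
#' the population mean of \eqn{w} is exactly 1 and the stated coefficients are
#' the population regression coefficients that a Lande-Arnold fit on
#' relativized fitness estimates.
#'
#' @param n_individuals number of plants per year.
#' @param year_labels character or integer vector of year labels.
#' @param mu_leafout,sd_leafout mean/SD of true leaf-out day (day of year).
#' @param mu_ffd,sd_ffd mean/SD of true first flowering day.
#' @param rho within-year correlation between leaf-out day and first
#'   flowering day, in \[-1, 1\].
#' @param mu_lnsize,sd_lnsize mean/SD of ln aboveground volume.
#' @param beta_L,beta_F,beta_size linear selection coefficients.
#' @param gamma_LL,gamma_FF quadratic selection coefficients (the \eqn{\gamma}
#'   scale, i.e. twice the regression coefficient on \eqn{z^2}).
#' @param gamma_LF correlational selection coefficient.
#' @param mean_fitness expected seed count at the population mean phenotype.
#' @param zero_inflation_pi probability that an individual produces zero seeds
#'   irrespective of phenotype, in \[0, 1).
#' @param dispersion_k negative-binomial shape (smaller = more overdispersed).
#' @param visit_interval_days days between census visits (>= 1).
#' @param leaflet_count_range integer pair: range of total leaflet counts.
#' @param unfolding_days_range numeric pair: days from first to last leaflet
#'   unfolding, drawn per individual.
#' @param holes_rate expected seed-predator entry holes per seed.
#' @param prop_pods_open probability a pod has opened before collection.
#' @param max_seeds_per_fruit seeds are packed into fruits of at most this many.
#' @param rng_seed integer seed; each sub-generator derives its own stream
#'   from it so stages are independently reproducible.
#'
#' @return An object of class `phenosel_simconfig` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, rng_seed = 1)
#' traits <- generate_traits(cfg)
sim_config <- function(n_individuals = 200,
                       year_labels = c("2013", "2014", "2015"),
                       mu_leafout = 110, sd_leafout = 6,
                       mu_ffd = 126, sd_ffd = 7,
                       rho = 0.4,
                       mu_lnsize = 6, sd_lnsize = 0.8,
                       beta_L = 0, beta_F = 0, beta_size = 0,
                       gamma_LL = 0, gamma_FF = 0, gamma_LF = 0,
                       mean_fitness = 8,
                       zero_inflation_pi = 0.4,
                       dispersion_k = 1.5,
                       visit_interval_days = 4,
                       leaflet_count_range = c(6L, 16L),
                       unfolding_days_range = c(7, 14),
                       holes_rate = 0.2,
                       prop_pods_open = 0.3,
                       max_seeds_per_fruit = 6L,
                       rng_seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), year_labels = as.character(year_labels),
    mu_leafout = mu_leafout, sd_leafout = sd_leafout,
    mu_ffd = mu_ffd, sd_ffd = sd_ffd, rho = rho,
    mu_lnsize = mu_lnsize, sd_lnsize = sd_lnsize,
    beta_L = beta_L, beta_F = beta_F, beta_size = beta_size,
    gamma_LL = gamma_LL, gamma_FF = gamma_FF, gamma_LF = gamma_LF,
    mean_fitness = mean_fitness, zero_inflation_pi = zero_inflation_pi,
    dispersion_k = dispersion_k,
    visit_interval_days = as.integer(visit_interval_days),
    leaflet_count_range = as.integer(leaflet_count_range),
    unfolding_days_range = as.numeric(unfolding_days_range),
    holes_rate = holes_rate, prop_pods_open = prop_pods_open,
    max_seeds_per_fruit = as.integer(max_seeds_per_fruit),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "phenosel_simconfig"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "phenosel_simconfig"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(length(cfg$n_individuals) == 1 && !is.na(cfg$n_individuals) && cfg$n_individuals >= 2,
      "n_individuals must be >= 2")
  chk(length(cfg$year_labels) >= 1 && !anyDuplicated(cfg$year_labels),
      "year_labels must be non-empty and unique")
  chk(is.finite(cfg$sd_leafout) && cfg$sd_leafout > 0, "sd_leafout must be > 0")
  chk(is.finite(cfg$sd_ffd) && cfg$sd_ffd > 0, "sd_ffd must be > 0")
  chk(is.finite(cfg$sd_lnsize) && cfg$sd_lnsize > 0, "sd_lnsize must be > 0")
  chk(is.finite(cfg$rho) && cfg$rho >= -1 && cfg$rho <= 1, "rho must be in [-1, 1]")
  chk(cfg$zero_inflation_pi >= 0 && cfg$zero_inflation_pi < 1,
      "zero_inflation_pi must be in [0, 1)")
  chk(is.finite(cfg$dispersion_k) && cfg$dispersion_k > 0, "dispersion_k must be > 0")
  chk(cfg$mean_fitness >= 0, "mean_fitness must be >= 0")
  chk(cfg$visit_interval_days >= 1, "visit_interval_days must be >= 1")
  chk(length(cfg$leaflet_count_range) == 2 && cfg$leaflet_count_range[1] >= 2 &&
        diff(cfg$leaflet_count_range) >= 0, "leaflet_count_range must be an increasing pair >= 2")
  chk(cfg$holes_rate >= 0, "holes_rate must be >= 0")
  chk(cfg$prop_pods_open >= 0 && cfg$prop_pods_open <= 1, "prop_pods_open must be in [0, 1]")
  chk(is.finite(cfg$rng_seed), "rng_seed must be a finite integer")
  invisible(cfg)
}

# One named RNG stream per sub-generator: a small deterministic hash of the
# stream name folded into the master seed, kept below .Machine$integer.max.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 257)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Write / read a simulation configuration as a plain-text key:value file
#'
#' @param cfg a `phenosel_simconfig`.
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `phenosel_simconfig`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  lines <- vapply(names(cfg), function(nm) {
    paste0(nm, ": ", paste(cfg[[nm]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- parse_keyvalue_file(path)
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  sim_config(
    n_individuals = num(kv$n_individuals),
    year_labels = strsplit(kv$year_labels, ",", fixed = TRUE)[[1]],
    mu_leafout = num(kv$mu_leafout), sd_leafout = num(kv$sd_leafout),
    mu_ffd = num(kv$mu_ffd), sd_ffd = num(kv$sd_ffd), rho = num(kv$rho),
    mu_lnsize = num(kv$mu_lnsize), sd_lnsize = num(kv$sd_lnsize),
    beta_L = num(kv$beta_L), beta_F = num(kv$beta_F), beta_size = num(kv$beta_size),
    gamma_LL = num(kv$gamma_LL), gamma_FF = num(kv$gamma_FF), gamma_LF = num(kv$gamma_LF),
    mean_fitness = num(kv$mean_fitness),
    zero_inflation_pi = num(kv$zero_inflation_pi),
    dispersion_k = num(kv$dispersion_k),
    visit_interval_days = num(kv$visit_interval_days),
    leaflet_count_range = num(kv$leaflet_count_range),
    unfolding_days_range = num(kv$unfolding_days_range),
    holes_rate = num(kv$holes_rate), prop_pods_open = num(kv$prop_pods_open),
    max_seeds_per_fruit = num(kv$max_seeds_per_fruit),
    rng_seed = num(kv$rng_seed)
  )
}

# "key: value" per line; '#' starts a comment; blank lines ignored.
parse_keyvalue_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop("malformed config line (expected 'key: value'): ", ln, call. = FALSE)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    out[[key]] <- val
  }
  out
}
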