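#' Prepare a PlantSeason table for selection analysis
#'
#' Drops rows with missing traits, fitness or size, ln-transforms size,
#' standardizes traits and relativizes fitness under the requested scheme.
#' Under the `"local"` scheme moments are computed within year and each year
#' is analyzed (and bootstrapped) separately; under `"global"` moments are
#' pooled and a single fit across years is used.
#'
#' @param data PlantSeason data.frame with columns `individual_id`, `year`,
#'   `leaf_out_day`, `first_flowering_day`, `development_time`,
#'   `aboveground_volume`, `fitness_intact_seeds`.
#' @param scheme `"local"` or `"global"`.
#' @return data.frame with z-scored trait columns (`z_L`, `z_F`, `z_dev`,
#'   `z_size`) and relative fitness `w`.
#' @export
prepare_selection_data <- function(data, scheme = c("local", "global")) {
  scheme <- match.arg(scheme)
  need <- c("individual_id", "year", "leaf_out_day", "first_flowering_day",
            "development_time", "aboveground_volume", "fitness_intact_seeds")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("prepare_selection_data: missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(data[, need])
  d <- data[keep, need]
  if (any(d$aboveground_volume <= 0)) {
    stop("prepare_selection_data: aboveground_volume must be > 0 for ln-transform",
         call. = FALSE)
  }
  grp <- if (scheme == "local") d$year else NULL
  d$z_L <- standardize(d$leaf_out_day, scheme, grp)
  d$z_F <- standardize(d$first_flowering_day, scheme, grp)
  d$z_dev <- standardize(d$development_time, scheme, grp)
  d$z_size <- standardize(log(d$aboveground_volume), scheme, grp)
  d$w <- relativize(d$fitness_intact_seeds, scheme, grp)
  attr(d, "scheme") <- scheme
  d
}

trait_z_column <- function(trait) {
  switch(trait,
         leaf_out_day = "z_L",
         first_flowering_day = "z_F",
         development_time = "z_dev",
         stop("unknown trait: ", trait, call. = FALSE))
}

#' Total selection on one trait (differential + quadratic term)
#'
#' Linear selection differentials come from `w ~ z (+ z_size)` and the
#' quadratic coefficient from the extended model `w ~ z + z^2 (+ z_size)`;
#' the two models are fitted separately and their estimates reported side by
#' side, with the squared-term coefficient doubled onto the gamma scale.
#' With `include_size = FALSE` the size covariate is omitted (the
#' supplementary "without size" variant; supported, not validated).
#'
#' @param data PlantSeason data.frame (see [prepare_selection_data()]).
#' @param trait `"leaf_out_day"`, `"first_flowering_day"` or
#'   `"development_time"`.
#' @param scheme standardization scheme, `"local"` or `"global"`.
#' @param include_size include ln-size as a covariate (default TRUE).
#' @param quadratic also fit the extended model with the squared term.
#' @param n_replicates BCa bootstrap replicates; 0 skips interval estimation.
#' @param level confidence level.
#' @param seed integer seed driving the per-stratum bootstrap streams.
#' @return a selection table: one row per term x stratum with `family`,
#'   `scheme`, `year`, `term`, `estimate`, `bca_lower`, `bca_upper`,
#'   `significant`, `doubled`, `vif`, `n`, `n_replicates`.
#' @export
total_selection <- function(data, trait, scheme = c("local", "global"),
                            include_size = TRUE, quadratic = TRUE,
                            n_replicates = 0, level = 0.95, seed = 1L) {
  scheme <- match.arg(scheme)
  d <- if (!is.null(attr(data, "scheme"))) data else prepare_selection_data(data, scheme)
  zc <- trait_z_column(trait)
  family <- paste0("total_", switch(trait, leaf_out_day = "leafout",
                                    first_flowering_day = "ffd",
                                    development_time = "devtime"))
  fit_by_stratum(d, scheme, family, function(s) {
    z <- s[[zc]]
    lin <- cbind(intercept = 1, z = z)
    colnames(lin)[2] <- trait
    if (include_size) lin <- cbind(lin, size = s$z_size)
    specs <- list(list(design = lin, model = "linear",
                       report = stats::setNames(colnames(lin)[-1], colnames(lin)[-1]),
                       double = character(0)))
    if (quadratic) {
      quad <- cbind(intercept = 1, z = z, z2 = z^2)
      colnames(quad)[2:3] <- c(trait, paste0(trait, "^2"))
      if (include_size) quad <- cbind(quad, size = s$z_size)
      specs <- c(specs, list(list(design = quad, model = "quadratic",
                                  report = stats::setNames(paste0(trait, "^2"),
                                                           paste0(trait, "^2")),
                                  double = paste0(trait, "^2"))))
    }
    specs
  }, n_replicates, level, seed)
}

#' Direct selection gradients (multiple regression)
#'
#' Direct linear gradients come from `w ~ z_L + z_F (+ z_size)`. The
#' `"correlational"` variant adds the interaction `z_L * z_F`; `"full"` adds
#' the two squared terms as well. Linear gradients are always reported from
#' the linear model, quadratic/interaction terms from the extended model.
#' Squared-term coefficients are doubled in the report; the interaction is
#' doubled only when `double_interaction = TRUE` (sensitivity switch — the
#' convention covers squared terms).
#'
#' @inheritParams total_selection
#' @param terms `"linear"`, `"correlational"` or `"full"`.
#' @param double_interaction also double the interaction coefficient.
#' @return a selection table (see [total_selection()]).
#' @export
direct_selection <- function(data, scheme = c("local", "global"),
                             terms = c("linear", "correlational", "full"),
                             include_size = TRUE, double_interaction = FALSE,
                             n_replicates = 0, level = 0.95, seed = 1L) {
  scheme <- match.arg(scheme)
  terms <- match.arg(terms)
  d <- if (!is.null(attr(data, "scheme"))) data else prepare_selection_data(data, scheme)
  family <- paste0("direct_", terms)
  inter <- "leaf_out_day:first_flowering_day"
  fit_by_stratum(d, scheme, family, function(s) {
    lin <- cbind(intercept = 1, L = s$z_L, F = s$z_F)
    colnames(lin)[2:3] <- c("leaf_out_day", "first_flowering_day")
    if (include_size) lin <- cbind(lin, size = s$z_size)
    specs <- list(list(design = lin, model = "linear",
                       report = stats::setNames(colnames(lin)[-1], colnames(lin)[-1]),
                       double = character(0)))
    if (terms != "linear") {
      ext <- cbind(intercept = 1, L = s$z_L, F = s$z_F)
      extra <- c(inter)
      ext <- cbind(ext, LF = s$z_L * s$z_F)
      if (terms == "full") {
        ext <- cbind(ext, L2 = s$z_L^2, F2 = s$z_F^2)
        extra <- c("leaf_out_day^2", "first_flowering_day^2", extra)
      }
      cn <- c("intercept", "leaf_out_day", "first_flowering_day", inter)
      if (terms == "full") cn <- c("intercept", "leaf_out_day", "first_flowering_day",
                                   inter, "leaf_out_day^2", "first_flowering_day^2")
      colnames(ext) <- cn
      if (include_size) ext <- cbind(ext, size = s$z_size)
      dbl <- grep("\\^2$", extra, value = TRUE)
      if (double_interaction) dbl <- c(dbl, inter)
      specs <- c(specs, list(list(design = ext, model = "extended",
                                  report = stats::setNames(extra, extra),
                                  double = dbl)))
    }
    specs
  }, n_replicates, level, seed)
}

#' Selection on development time
#'
#' Total-selection model with standardized development time (first flowering
#' day minus leaf-out day) as the trait; shares the [total_selection()] code
#' path.
#'
#' @inheritParams total_selection
#' @export
devtime_selection <- function(data, scheme = c("local", "global"),
                              include_size = TRUE, quadratic = TRUE,
                              n_replicates = 0, level = 0.95, seed = 1L) {
  total_selection(data, "development_time", scheme, include_size, quadratic,
                  n_replicates, level, seed)
}

# Shared stratum loop: build model specs, fit, bootstrap, assemble rows.
# spec_builder(stratum_df) returns a list of specs, each a list(design, model,
# report = named map reported-term -> design column, double = terms to x2).
fit_by_stratum <- function(d, scheme, family, spec_builder, n_replicates, level, seed) {
  strata <- if (scheme == "local") split(d, d$year) else list(all = d)
  rows <- list()
  for (snm in names(strata)) {
    s <- strata[[snm]]
    specs <- spec_builder(s)
    designs <- lapply(specs, `[[`, "design")
    names(designs) <- vapply(specs, `[[`, character(1), "model")
    w <- s$w
    boot <- NULL
    if (n_replicates > 0) {
      boot <- boot_ols_designs(designs, w, n_replicates,
                               seed = stream_seed(seed, paste(family, scheme, snm)))
    }
    for (sp in specs) {
      X <- sp$design
      fit <- fit_ols(X, w)
      vifs <- if (ncol(X) >= 3) vif(X[, -1, drop = FALSE]) else
        stats::setNames(rep(NA_real_, ncol(X) - 1), colnames(X)[-1])
      for (term in names(sp$report)) {
        col <- sp$report[[term]]
        dbl <- term %in% sp$double
        mult <- if (dbl) 2 else 1
        est <- mult * unname(fit$coefficients[col])
        lo <- hi <- NA_real_
        sig <- NA
        if (!is.null(boot)) {
          ci <- bca_interval(mult * boot$reps[[sp$model]][, col],
                             mult * boot$orig[[sp$model]][[col]],
                             mult * boot$jack[[sp$model]][, col], level)
          lo <- ci[1]; hi <- ci[2]
          sig <- significance(c(lo, hi))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, scheme = scheme,
          year = if (scheme == "local") snm else "all",
          model = sp$model, term = term, estimate = est,
          bca_lower = lo, bca_upper = hi, significant = sig,
          doubled = dbl, vif = unname(vifs[col]),
          n = nrow(s), n_replicates = n_replicates,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenosel_table", class(out))
  out
}

#' Compare a direct-selection estimate with a total-selection interval
#'
#' The indirect-selection decision rule: direct and total selection on a
#' trait are considered to differ — implying selection acts indirectly via
#' the correlated trait — iff the direct point estimate falls outside the
#' closed BCa interval of the total estimate.
#'
#' @param direct one row of a direct-selection table (or a list with
#'   `term`, `year`, `scheme`, `estimate`).
#' @param total the matching row of a total-selection table (needs
#'   `bca_lower`, `bca_upper` in addition).
#' @return list: `flagged` (logical), `interpretation` (character).
#' @export
compare_direct_vs_total <- function(direct, total) {
  for (f in c("term", "year", "scheme")) {
    if (!identical(as.character(direct[[f]]), as.character(total[[f]]))) {
      stop("compare_direct_vs_total: mismatched ", f, " ('", direct[[f]],
           "' vs '", total[[f]], "')", call. = FALSE)
    }
  }
  if (is.na(total$bca_lower) || is.na(total$bca_upper)) {
    stop("compare_direct_vs_total: total estimate has no BCa interval", call. = FALSE)
  }
  est <- direct$estimate
  flagged <- est < total$bca_lower || est > total$bca_upper
  other <- if (grepl("leaf_out", as.character(direct$term))) "first flowering day" else "leaf-out day"
  list(flagged = flagged,
       interpretation = if (flagged) paste0("indirect via ", other) else "no difference detected")
}

#' Fit all six selection-model families
#'
#' Convenience driver: total selection on leaf-out day, first flowering day
#' and development time, plus direct linear, correlational and full
#' (quadratic + interaction) gradient models, under one scheme.
#'
#' @inheritParams total_selection
#' @param double_interaction passed to [direct_selection()].
#' @return one combined selection table.
#' @export
selection_tables <- function(data, scheme = c("local", "global"),
                             include_size = TRUE, n_replicates = 0,
                             level = 0.95, seed = 1L, double_interaction = FALSE) {
  scheme <- match.arg(scheme)
  d <- prepare_selection_data(data, scheme)
  out <- rbind(
    total_selection(d, "leaf_out_day", scheme, include_size, TRUE, n_replicates, level, seed),
    total_selection(d, "first_flowering_day", scheme, include_size, TRUE, n_replicates, level, seed),
    devtime_selection(d, scheme, include_size, TRUE, n_replicates, level, seed),
    direct_selection(d, scheme, "linear", include_size, double_interaction, n_replicates, level, seed),
    direct_selection(d, scheme, "correlational", include_size, double_interaction, n_replicates, level, seed),
    direct_selection(d, scheme, "full", include_size, double_interaction, n_replicates, level, seed)
  )
  class(out) <- c("phenosel_table", class(out))
  out
}

#' Per-year trait correlations
#'
#' Pearson correlation between untransformed leaf-out day and first
#' flowering day, per year, with t-test.
#'
#' @param data PlantSeason data.frame.
#' @return data.frame: `year`, `r`, `t`, `df`, `p`, `n`.
#' @export
trait_correlations <- function(data) {
  out <- lapply(split(data, data$year), function(s) {
    ok <- stats::complete.cases(s$leaf_out_day, s$first_flowering_day)
    pc <- pearson_correlation(s$leaf_out_day[ok], s$first_flowering_day[ok])
    data.frame(year = s$year[1], r = pc$r, t = pc$t, df = pc$df, p = pc$p,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
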