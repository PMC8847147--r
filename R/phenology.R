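#' Fit the leaflet-unfolding model
#'
#' Ordinary least squares of the number of unfolded leaflets at the first
#' post-leaf-out recording on the total leaflet count and its square:
#' `unfolded ~ 1 + total + total^2`. The residuals of this model are the
#' deviations used to place each plant's leaf-out day inside its recording
#' interval: a plant with more leaflets unfolded than predicted for its size
#' must have started unfolding earlier in the interval.
#'
#' @param leaflets_total,leaflets_unfolded vectors of first-recording counts
#'   (one element per plant).
#' @return object of class `phenosel_unfolding` with elements `coefficients`
#'   (intercept, total, total^2), `residuals`, `sigma`.
#' @export
fit_unfolding_model <- function(leaflets_total, leaflets_unfolded) {
  stopifnot(length(leaflets_total) == length(leaflets_unfolded))
  if (length(unique(leaflets_total)) < 3) {
    stop("fit_unfolding_model: need >= 3 distinct total-leaflet values to fit ",
         "a quadratic; got ", length(unique(leaflets_total)), call. = FALSE)
  }
  X <- cbind(intercept = 1, total = leaflets_total, total_sq = leaflets_total^2)
  fit <- fit_ols(X, leaflets_unfolded)
  structure(list(coefficients = fit$coefficients,
                 residuals = fit$residuals,
                 sigma = sqrt(sum(fit$residuals^2) / max(1, length(leaflets_unfolded) - 3))),
            class = "phenosel_unfolding")
}

#' Predict unfolded-leaflet count from total leaflets
#' @param model a `phenosel_unfolding` fit.
#' @param leaflets_total vector of totals.
#' @return predicted unfolded counts.
#' @export
predict_unfolded <- function(model, leaflets_total) {
  stopifnot(inherits(model, "phenosel_unfolding"))
  b <- model$coefficients
  unname(b[1] + b[2] * leaflets_total + b[3] * leaflets_total^2)
}

# Empirical-percentile placement shared by leaf-out and flowering assignment.
# score: larger value => event earlier in the interval. Ranks are computed over
# the cohort passed in (one year), ties broken by id order for determinism, and
# mapped to p = (rank - 0.5)/n in (0, 1). The assigned day is
# interval_end - p * interval_length, always inside (interval_start, interval_end].
percentile_day <- function(score, interval_start, interval_end, ids = seq_along(score)) {
  n <- length(score)
  stopifnot(length(interval_start) == n, length(interval_end) == n)
  if (any(interval_end < interval_start)) {
    stop("percentile_day: interval_end must be >= interval_start", call. = FALSE)
  }
  r <- order(order(score, ids))            # rank of score with ties broken by id order
  p <- (r - 0.5) / n
  interval_end - p * (interval_end - interval_start)
}

#' Assign a continuous leaf-out day within each plant's recording interval
#'
#' Plants are placed inside the interval between the last visit with no
#' unfolded leaflets and the first visit with at least one, by the empirical
#' percentile of their deviation from the unfolding model: a larger deviation
#' (more leaflets unfolded than predicted) maps monotonically to an earlier
#' day. Percentiles are computed over the cohort supplied in the call (use
#' one year at a time; census schedules differ among years).
#'
#' @param prev_visit_day last visit day with zero unfolded leaflets.
#' @param first_unfolded_visit_day first visit day with >= 1 unfolded leaflet.
#' @param observed_unfolded unfolded count at that first visit.
#' @param leaflets_total total leaflet count.
#' @param model a [fit_unfolding_model()] fit.
#' @param ids identifiers used to break ties in deviation deterministically.
#' @return vector of continuous leaf-out days, each in
#'   `(prev_visit_day, first_unfolded_visit_day]`.
#' @export
assign_leaf_out_day <- function(prev_visit_day, first_unfolded_visit_day,
                                observed_unfolded, leaflets_total, model,
                                ids = seq_along(observed_unfolded)) {
  if (missing(model) || is.null(model)) stop("assign_leaf_out_day: model is required", call. = FALSE)
  stopifnot(all(observed_unfolded >= 1))
  # zero-length intervals collapse to the single candidate day inside percentile_day
  if (any(prev_visit_day > first_unfolded_visit_day)) {
    stop("assign_leaf_out_day: prev_visit_day must not exceed first_unfolded_visit_day",
         call. = FALSE)
  }
  dev <- observed_unfolded - predict_unfolded(model, leaflets_total)
  percentile_day(dev, prev_visit_day, first_unfolded_visit_day, ids)
}

#' Assign a continuous first flowering day from bud size at the prior visit
#'
#' Same percentile-mapping contract as [assign_leaf_out_day()]: a larger bud
#' at the visit before the first open flower means flowering started earlier
#' in the interval. Missing bud sizes fall back to the interval midpoint and
#' are flagged.
#'
#' @param bud_size_at_prev_visit largest-bud length (mm) at the prior visit;
#'   `NA` allowed (midpoint fallback).
#' @param prev_visit_day,first_flower_visit_day the bracketing visit days.
#' @param ids tie-break identifiers.
#' @return list with `day` (continuous first flowering day in
#'   `(prev, first]`) and `midpoint_fallback` (logical flag per plant).
#' @export
assign_ffd_from_bud <- function(bud_size_at_prev_visit, prev_visit_day,
                                first_flower_visit_day,
                                ids = seq_along(bud_size_at_prev_visit)) {
  if (any(prev_visit_day > first_flower_visit_day)) {
    stop("assign_ffd_from_bud: prev_visit_day must not exceed first_flower_visit_day",
         call. = FALSE)
  }
  miss <- is.na(bud_size_at_prev_visit)
  day <- rep(NA_real_, length(bud_size_at_prev_visit))
  if (any(!miss)) {
    day[!miss] <- percentile_day(bud_size_at_prev_visit[!miss],
                                 prev_visit_day[!miss], first_flower_visit_day[!miss],
                                 ids[!miss])
  }
  day[miss] <- (prev_visit_day[miss] + first_flower_visit_day[miss]) / 2
  list(day = day, midpoint_fallback = miss)
}

#' Fit and apply the grazed-plant flowering-day model
#'
#' For plants grazed before their first flower was seen, first flowering day
#' is predicted from the relationship — fitted on intact plants — between
#' assigned flowering day and bud size, the day of year of the bud
#' observation, and ln aboveground volume.
#'
#' @param ffd,bud_size,observation_day,aboveground_volume training vectors
#'   from intact plants.
#' @return object of class `phenosel_grazed_ffd` (OLS coefficients).
#' @export
fit_grazed_ffd_model <- function(ffd, bud_size, observation_day, aboveground_volume) {
  if (length(ffd) == 0) stop("fit_grazed_ffd_model: no intact plants to train on", call. = FALSE)
  ok <- stats::complete.cases(ffd, bud_size, observation_day, aboveground_volume)
  if (sum(ok) < 4) stop("fit_grazed_ffd_model: need >= 4 complete intact rows", call. = FALSE)
  X <- cbind(intercept = 1, bud_size = bud_size[ok],
             observation_day = observation_day[ok],
             ln_volume = log(aboveground_volume[ok]))
  fit <- fit_ols(X, ffd[ok])
  structure(list(coefficients = fit$coefficients), class = "phenosel_grazed_ffd")
}

#' @rdname fit_grazed_ffd_model
#' @param model a `phenosel_grazed_ffd` fit.
#' @return `estimate_ffd_grazed()` returns the point predictions (`NA`, with a
#'   message, for plants missing any predictor).
#' @export
estimate_ffd_grazed <- function(bud_size, observation_day, aboveground_volume, model) {
  stopifnot(inherits(model, "phenosel_grazed_ffd"))
  b <- model$coefficients
  pred <- b[1] + b[2] * bud_size + b[3] * observation_day + b[4] * log(aboveground_volume)
  miss <- !stats::complete.cases(bud_size, observation_day, aboveground_volume)
  if (any(miss)) {
    message("estimate_ffd_grazed: ", sum(miss), " plant(s) missing a predictor; excluded (NA)")
    pred[miss] <- NA_real_
  }
  unname(pred)
}

#' Aboveground volume of a plant
#'
#' Cylinder volume of the focal shoot times the number of shoots:
#' `(0.5 * diameter)^2 * height * pi * n_shoots`. Diameter in mm, height in
#' cm; the product's units are those the selection models ln-transform, so
#' the unit mix only shifts the intercept.
#'
#' @param diameter shoot diameter (mm), >= 0.
#' @param height shoot height (cm), >= 0.
#' @param n_shoots number of shoots, >= 0.
#' @return volume; 0 iff any input is 0.
#' @export
#' @examples
#' aboveground_volume(2, 10, 3)  # 30 * pi
aboveground_volume <- function(diameter, height, n_shoots) {
  if (any(c(diameter, height, n_shoots) < 0, na.rm = TRUE)) {
    stop("aboveground_volume: inputs must be >= 0", call. = FALSE)
  }
  (0.5 * diameter)^2 * height * pi * n_shoots
}

#' Impute final shoot height for grazed plants
#'
#' Height of plants grazed before the last spring recording is predicted from
#' the height~diameter OLS relationship of nongrazed plants. Plants grazed
#' *after* the last spring recording instead keep their maximum recorded
#' spring height (`use_max_spring` flag).
#'
#' @param height,diameter training vectors from nongrazed plants
#'   (`fit_height_diameter_model`).
#' @return a `phenosel_height_model`.
#' @export
fit_height_diameter_model <- function(height, diameter) {
  ok <- stats::complete.cases(height, diameter)
  if (sum(ok) < 2) stop("fit_height_diameter_model: no nongrazed plants to train on", call. = FALSE)
  fit <- fit_ols(cbind(intercept = 1, diameter = diameter[ok]), height[ok])
  structure(list(coefficients = fit$coefficients), class = "phenosel_height_model")
}

#' @rdname fit_height_diameter_model
#' @param model a `phenosel_height_model`.
#' @param use_max_spring logical per plant: grazed after the last spring
#'   recording, so use `max_spring_height` instead of the model.
#' @param max_spring_height maximum height recorded in spring.
#' @export
impute_grazed_height <- function(diameter, model, use_max_spring = FALSE,
                                 max_spring_height = NULL) {
  stopifnot(inherits(model, "phenosel_height_model"))
  pred <- unname(model$coefficients[1] + model$coefficients[2] * diameter)
  if (any(use_max_spring)) {
    if (is.null(max_spring_height)) {
      stop("impute_grazed_height: max_spring_height required when use_max_spring is set",
           call. = FALSE)
    }
    pred[use_max_spring] <- max_spring_height[use_max_spring]
  }
  pred
}

#' Estimate per-individual phenology traits from a census table
#'
#' The end-to-end conversion of discrete census records into the per-season
#' analysis table: per year, it fits the unfolding model on first-post-leaf-out
#' recordings, assigns continuous leaf-out days by deviation percentile,
#' assigns first flowering days by bud-size percentile (grazed plants via the
#' intact-plant model when possible), computes development time, and merges
#' shoot measurements into aboveground volume (grazed heights imputed).
#'
#' Plants never seen with an unfolded leaflet, or already unfolded at their
#' first visit (no bracketing interval), get `NA` with a reason in
#' `leaf_out_flag`.
#'
#' @param census census data.frame (see [generate_census()] for columns;
#'   truth columns are ignored if present).
#' @param shoots optional shoot table (see [generate_shoots()]).
#' @return a `PlantSeason` data.frame: `individual_id`, `year`,
#'   `leaf_out_day`, `first_flowering_day`, `development_time`,
#'   `aboveground_volume`, `leaf_out_flag`, `ffd_flag`.
#' @export
estimate_phenology <- function(census, shoots = NULL) {
  required <- c("individual_id", "year", "day", "leaflets_total",
                "leaflets_unfolded", "bud_size", "flowers_open", "grazed")
  miss <- setdiff(required, names(census))
  if (length(miss)) stop("estimate_phenology: census is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  census <- census[order(census$year, census$individual_id, census$day), ]
  years <- unique(census$year)
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    cs <- census[census$year == yr, ]
    out[[k]] <- estimate_phenology_one_year(cs, yr)
  }
  ps <- do.call(rbind, out)
  rownames(ps) <- NULL
  if (!is.null(shoots)) {
    ps <- merge_shoot_volume(ps, shoots)
  }
  ps
}

estimate_phenology_one_year <- function(cs, yr) {
  ids <- unique(cs$individual_id)
  n <- length(ids)
  by_id <- split(cs, factor(cs$individual_id, levels = ids))
  first_day <- prev_day <- obs_unf <- tot <- rep(NA_real_, n)
  flag <- rep("ok", n)
  ffd_first <- ffd_prev <- ffd_bud <- rep(NA_real_, n)
  ffd_flag <- rep("ok", n)
  grazed_any <- rep(FALSE, n)
  for (i in seq_len(n)) {
    v <- by_id[[i]]
    if (any(diff(v$day) <= 0)) stop("estimate_phenology: visits not strictly increasing for ",
                                    ids[i], call. = FALSE)
    grazed_any[i] <- any(v$grazed)
    j <- which(v$leaflets_unfolded >= 1)
    if (length(j) == 0) {
      flag[i] <- "never_unfolded"
    } else if (j[1] == 1) {
      flag[i] <- "no_prior_visit"
    } else {
      first_day[i] <- v$day[j[1]]
      prev_day[i] <- v$day[j[1] - 1]
      obs_unf[i] <- v$leaflets_unfolded[j[1]]
      tot[i] <- v$leaflets_total[j[1]]
    }
    jf <- which(v$flowers_open >= 1)
    if (length(jf) == 0) {
      ffd_flag[i] <- if (grazed_any[i]) "grazed_unflowered" else "never_flowered"
    } else if (jf[1] == 1) {
      ffd_flag[i] <- "no_prior_visit"
    } else {
      ffd_first[i] <- v$day[jf[1]]
      ffd_prev[i] <- v$day[jf[1] - 1]
      ffd_bud[i] <- v$bud_size[jf[1] - 1]
    }
  }

  leaf_out <- rep(NA_real_, n)
  ok <- !is.na(first_day)
  if (sum(ok) >= 3 && length(unique(tot[ok])) >= 3) {
    um <- fit_unfolding_model(tot[ok], obs_unf[ok])
    leaf_out[ok] <- assign_leaf_out_day(prev_day[ok], first_day[ok],
                                        obs_unf[ok], tot[ok], um, ids[ok])
  } else if (any(ok)) {
    # too few plants for the quadratic model: midpoint of the interval
    leaf_out[ok] <- (prev_day[ok] + first_day[ok]) / 2
    flag[ok] <- "midpoint_no_model"
  }

  ffd <- rep(NA_real_, n)
  okf <- !is.na(ffd_first)
  if (any(okf)) {
    af <- assign_ffd_from_bud(ffd_bud[okf], ffd_prev[okf], ffd_first[okf], ids[okf])
    ffd[okf] <- af$day
    ffd_flag[okf][af$midpoint_fallback] <- "bud_missing_midpoint"
  }

  data.frame(
    individual_id = ids, year = yr,
    leaf_out_day = leaf_out, first_flowering_day = ffd,
    development_time = ffd - leaf_out,
    leaf_out_flag = flag, ffd_flag = ffd_flag,
    grazed = grazed_any,
    stringsAsFactors = FALSE
  )
}

merge_shoot_volume <- function(ps, shoots) {
  req <- c("individual_id", "year", "shoot_height", "shoot_diameter", "n_shoots")
  miss <- setdiff(req, names(shoots))
  if (length(miss)) stop("estimate_phenology: shoot table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(shoots$grazed_spring)) shoots$grazed_spring <- FALSE
  if (is.null(shoots$grazed_after_spring)) shoots$grazed_after_spring <- FALSE
  height <- shoots$shoot_height
  needs_model <- shoots$grazed_spring & !shoots$grazed_after_spring
  if (any(needs_model)) {
    hm <- fit_height_diameter_model(shoots$shoot_height[!shoots$grazed_spring],
                                    shoots$shoot_diameter[!shoots$grazed_spring])
    height[needs_model] <- impute_grazed_height(shoots$shoot_diameter[needs_model], hm)
  }
  if (any(shoots$grazed_after_spring)) {
    height[shoots$grazed_after_spring] <- shoots$max_spring_height[shoots$grazed_after_spring]
  }
  shoots$aboveground_volume <- aboveground_volume(shoots$shoot_diameter, height, shoots$n_shoots)
  merge(ps, shoots[, c("individual_id", "year", "aboveground_volume")],
        by = c("individual_id", "year"), all.x = TRUE, sort = FALSE)
}
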