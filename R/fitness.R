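#' Seed-predation model
#'
#' Exponential saturation of the proportion of seeds preyed upon by the
#' seed-beetle larvae as a function of entry holes per seed, with the rate
#' constant fixed at 1.218 from prior calibration on intact fruits of the
#' same species. The constant is exposed for sensitivity analysis but not
#' re-estimated here.
#'
#' @param rate_constant positive rate of the exponential predation model.
#' @return object of class `phenosel_predation`.
#' @export
predation_model <- function(rate_constant = 1.218) {
  if (!is.numeric(rate_constant) || length(rate_constant) != 1 || rate_constant <= 0) {
    stop("predation_model: rate_constant must be a single positive number", call. = FALSE)
  }
  structure(list(rate_constant = rate_constant), class = "phenosel_predation")
}

#' Proportion of seeds preyed upon given entry holes per seed
#'
#' `1 - exp(-rate_constant * holes_per_seed)`; in \[0, 1), monotone increasing.
#'
#' @param holes_per_seed entry holes per seed, >= 0 (vectorized).
#' @param model a [predation_model()].
#' @return predation proportions.
#' @export
#' @examples
#' predation_proportion(1)    # 0.7042
#' predation_proportion(0.5)  # 0.4562
predation_proportion <- function(holes_per_seed, model = predation_model()) {
  stopifnot(inherits(model, "phenosel_predation"))
  if (any(holes_per_seed < 0, na.rm = TRUE)) {
    stop("predation_proportion: holes_per_seed must be >= 0", call. = FALSE)
  }
  1 - exp(-model$rate_constant * holes_per_seed)
}

#' Intact (undamaged) seeds for one individual's fruits
#'
#' The fitness measure: developed seeds not damaged by seed-predator larvae,
#' summed over fruits. Closed pods (`per_seed_holes_observed = TRUE`) are
#' counted directly: `n_seeds - n_entry_holes`, where `n_entry_holes` is the
#' number of damaged seeds. Opened pods only expose wall holes, so the intact
#' fraction is estimated from the exponential predation model:
#' `n_seeds * exp(-rate * n_entry_holes / n_seeds)`. Open-pod contributions
#' are fractional by design (not rounded). An opened pod with zero seeds
#' contributes 0 and is reported in `attr(, "zero_seed_open_pods")`.
#'
#' @param fruits data.frame of fruit records for ONE individual (columns
#'   `n_seeds`, `n_entry_holes`, `pod_opened`, `per_seed_holes_observed`).
#' @param model a [predation_model()].
#' @return nonnegative fitness value (0 for no fruits).
#' @export
#' @examples
#' intact_seeds(data.frame(n_seeds = 10, n_entry_holes = 5, pod_opened = TRUE,
#'                         per_seed_holes_observed = FALSE))  # 10 * exp(-0.609)
intact_seeds <- function(fruits, model = predation_model()) {
  if (is.null(fruits) || nrow(fruits) == 0) return(0)
  stopifnot(all(fruits$n_seeds >= 0), all(fruits$n_entry_holes >= 0))
  total <- 0
  zero_open <- 0L
  for (i in seq_len(nrow(fruits))) {
    s <- fruits$n_seeds[i]
    h <- fruits$n_entry_holes[i]
    if (isTRUE(fruits$per_seed_holes_observed[i]) && !isTRUE(fruits$pod_opened[i])) {
      total <- total + max(0, s - h)
    } else {
      if (s == 0) { zero_open <- zero_open + 1L; next }
      total <- total + s * (1 - predation_proportion(h / s, model))
    }
  }
  structure(total, zero_seed_open_pods = zero_open)
}

#' Per-individual fitness from a fruit table
#'
#' Applies [intact_seeds()] to every individual x year and returns a fitness
#' table suitable for merging into the PlantSeason table. Individuals present
#' in `individuals` but absent from `fruits` get fitness 0 (no fruits).
#'
#' @param fruits fruit record data.frame (see [generate_fruits()]).
#' @param model a [predation_model()].
#' @param individuals optional data.frame with `individual_id`, `year` giving
#'   the full set of analysis units.
#' @return data.frame: `individual_id`, `year`, `fitness_intact_seeds`.
#' @export
fitness_from_fruits <- function(fruits, model = predation_model(), individuals = NULL) {
  if (nrow(fruits)) {
    key <- interaction(fruits$individual_id, fruits$year, drop = TRUE)
    agg <- vapply(split(fruits, key), intact_seeds, numeric(1), model = model)
    first <- !duplicated(key)
    tab <- data.frame(individual_id = fruits$individual_id[first],
                      year = fruits$year[first],
                      fitness_intact_seeds = as.numeric(agg[as.character(key[first])]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(individual_id = character(0), year = character(0),
                      fitness_intact_seeds = numeric(0))
  }
  if (!is.null(individuals)) {
    out <- merge(individuals[, c("individual_id", "year")], tab,
                 by = c("individual_id", "year"), all.x = TRUE, sort = FALSE)
    out$fitness_intact_seeds[is.na(out$fitness_intact_seeds)] <- 0
    return(out)
  }
  tab
}
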