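#' Run the full selection-analysis pipeline from a config file
#'
#' Config-driven end-to-end run: either simulate a dataset (synthetic mode)
#' or read census/fruit/shoot CSVs (real mode), estimate phenology, compute
#' predation-corrected fitness, fit all six selection-model families under
#' the requested scheme(s) with BCa intervals, and write the outputs:
#' `plant_season.csv`, `selection_table.csv`, `correlations.csv`,
#' `comparison_flags.csv`, `table1.csv` and `manifest.json`. Identical config
#' and seed give byte-identical CSVs.
#'
#' Config keys (plain `key: value` text): `mode` (`synthetic` | `csv`),
#' `out_dir`, `seed`, `n_replicates`, `scheme` (`local`, `global` or
#' `local,global`), `include_size`, `double_interaction`; synthetic mode
#' accepts any [sim_config()] field; csv mode requires `census_csv`,
#' `fruits_csv` and optionally `shoots_csv`. A config naming both
#' `census_csv` and synthetic-mode `n_individuals` is rejected.
#'
#' @param config path to a config file, or an equivalent named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  kv <- if (is.character(config)) parse_keyvalue_file(config) else config
  mode <- kv$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "csv")) stop("run_pipeline: mode must be 'synthetic' or 'csv'",
                                             call. = FALSE)
  has_csv_inputs <- any(c("census_csv", "fruits_csv", "shoots_csv") %in% names(kv))
  sim_keys <- c("n_individuals", "beta_L", "beta_F", "beta_size", "rho", "mean_fitness")
  if (has_csv_inputs && mode == "synthetic") {
    stop("run_pipeline: config mixes synthetic mode with CSV inputs; choose one", call. = FALSE)
  }
  if (mode == "csv" && any(sim_keys %in% names(kv))) {
    stop("run_pipeline: config mixes CSV mode with synthetic-generator fields", call. = FALSE)
  }
  out_dir <- out_dir %||% kv$out_dir %||% stop("run_pipeline: out_dir required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(kv$seed %||% 1)
  B <- as.integer(kv$n_replicates %||% 10000)
  schemes <- strsplit(kv$scheme %||% "local", ",", fixed = TRUE)[[1]]
  include_size <- as.logical(kv$include_size %||% TRUE)
  double_interaction <- as.logical(kv$double_interaction %||% FALSE)
  warnings_log <- character(0)

  withCallingHandlers({
    if (mode == "synthetic") {
      cfg_args <- kv[intersect(names(kv), names(formals(sim_config)))]
      cfg_args <- lapply(cfg_args, function(v) {
        x <- strsplit(as.character(v), ",", fixed = TRUE)[[1]]
        num <- suppressWarnings(as.numeric(x))
        if (any(is.na(num))) x else num
      })
      cfg_args$rng_seed <- seed
      cfg <- do.call(sim_config, cfg_args)
      sim <- simulate_dataset(cfg)
      census <- sim$census; fruits <- sim$fruits; shoots <- sim$shoots
    } else {
      for (f in c("census_csv", "fruits_csv")) {
        if (is.null(kv[[f]])) stop("run_pipeline: missing required config key ", f, call. = FALSE)
        if (!file.exists(kv[[f]])) stop("run_pipeline: file not found: ", kv[[f]], call. = FALSE)
      }
      census <- utils::read.csv(kv$census_csv, stringsAsFactors = FALSE)
      fruits <- utils::read.csv(kv$fruits_csv, stringsAsFactors = FALSE)
      shoots <- if (!is.null(kv$shoots_csv)) {
        if (!file.exists(kv$shoots_csv)) stop("run_pipeline: file not found: ", kv$shoots_csv,
                                              call. = FALSE)
        utils::read.csv(kv$shoots_csv, stringsAsFactors = FALSE)
      } else NULL
    }
    census$year <- as.character(census$year)
    fruits$year <- as.character(fruits$year)
    if (!is.null(shoots)) shoots$year <- as.character(shoots$year)

    ps <- estimate_phenology(census, shoots)
    fit <- fitness_from_fruits(fruits, individuals = ps)
    ps <- merge(ps, fit, by = c("individual_id", "year"), all.x = TRUE, sort = FALSE)
    ps$fitness_intact_seeds[is.na(ps$fitness_intact_seeds)] <- 0
    ps <- ps[order(ps$year, ps$individual_id), ]

    tables <- do.call(rbind, lapply(schemes, function(sc) {
      selection_tables(ps, sc, include_size, B, seed = seed,
                       double_interaction = double_interaction)
    }))
    usable <- stats::complete.cases(ps[, c("leaf_out_day", "first_flowering_day",
                                           "aboveground_volume")])
    cors <- trait_correlations(ps[usable, ])
    flags <- comparison_flags(tables)
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  for (msg in warnings_log) warning(msg, call. = FALSE)

  write_table_csv(ps, file.path(out_dir, "plant_season.csv"))
  write_table_csv(tables, file.path(out_dir, "selection_table.csv"))
  write_table_csv(cors, file.path(out_dir, "correlations.csv"))
  write_table_csv(flags, file.path(out_dir, "comparison_flags.csv"))
  t1 <- render_table1(tables[tables$scheme == schemes[1], ])
  write_table_csv(t1, file.path(out_dir, "table1.csv"))

  manifest <- list(
    mode = mode, seed = seed, n_replicates = B, schemes = schemes,
    include_size = include_size, double_interaction = double_interaction,
    package_version = as.character(utils::packageVersion("phenosel")),
    n_per_year = as.list(table(ps$year)),
    config_digest = digest_config(kv),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(plant_season = ps, selection = tables, correlations = cors,
                 comparison = flags, table1 = t1, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic config digest without external dependencies: sum of char
# codes of the canonicalized key:value text, base-36 encoded
digest_config <- function(kv) {
  kv <- kv[order(names(kv))]
  txt <- paste(names(kv), vapply(kv, function(v) paste(v, collapse = ","), character(1)),
               sep = ":", collapse = ";")
  ints <- utf8ToInt(txt)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  sprintf("%x", h)
}

write_table_csv <- function(df, path) {
  utils::write.csv(format_full_precision(df), path, row.names = FALSE, quote = TRUE)
}

#' Group a selection table into a publication-style report
#'
#' Reshapes the long selection table into the familiar three-block layout —
#' (a) total selection on leaf-out day, (b) total selection on first
#' flowering day, (c) direct linear/nonlinear/correlational selection — with
#' estimate, lower and upper columns per year and a `significant` marker
#' (the bolding rule: BCa interval excludes zero). Missing model families are
#' emitted as NA rows with a warning.
#'
#' @param tables a selection table for a single scheme.
#' @return data.frame: `block`, `term`, then `<year>_estimate`,
#'   `<year>_lower`, `<year>_upper`, `<year>_significant` per year.
#' @export
render_table1 <- function(tables) {
  if (is.null(tables) || nrow(tables) == 0) stop("render_table1: empty input", call. = FALSE)
  if (length(unique(tables$scheme)) > 1) {
    stop("render_table1: pass a single-scheme table", call. = FALSE)
  }
  years <- sort(unique(tables$year))
  blocks <- list(
    list(block = "(a) Total selection: leaf-out day", family = c("total_leafout"),
         terms = c("leaf_out_day", "size", "leaf_out_day^2")),
    list(block = "(b) Total selection: first flowering day", family = c("total_ffd"),
         terms = c("first_flowering_day", "size", "first_flowering_day^2")),
    list(block = "(c) Direct selection", family = c("direct_linear", "direct_full"),
         terms = c("leaf_out_day", "first_flowering_day", "size",
                   "leaf_out_day^2", "first_flowering_day^2",
                   "leaf_out_day:first_flowering_day"))
  )
  rows <- list()
  for (bl in blocks) {
    sub <- tables[tables$family %in% bl$family, ]
    if (nrow(sub) == 0) {
      warning("render_table1: missing model family ", paste(bl$family, collapse = "/"),
              "; emitting NA rows", call. = FALSE)
    }
    for (term in bl$terms) {
      row <- list(block = bl$block, term = term)
      for (yr in years) {
        hit <- sub[sub$term == term & sub$year == yr, ]
        # linear terms in block (c) come from the linear model, not the full one
        if (nrow(hit) > 1) hit <- hit[order(match(hit$model, c("linear", "quadratic", "extended"))), ][1, ]
        if (nrow(hit) == 0) hit <- data.frame(estimate = NA_real_, bca_lower = NA_real_,
                                              bca_upper = NA_real_, significant = NA)
        row[[paste0(yr, "_estimate")]] <- hit$estimate[1]
        row[[paste0(yr, "_lower")]] <- hit$bca_lower[1]
        row[[paste0(yr, "_upper")]] <- hit$bca_upper[1]
        row[[paste0(yr, "_significant")]] <- hit$significant[1]
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direct-vs-total comparison flags for a combined selection table
#'
#' Applies [compare_direct_vs_total()] to every (trait, year, scheme)
#' combination present in both the direct-linear and total tables.
#'
#' @param tables combined selection table (needs BCa intervals on the total
#'   rows; rows without intervals are skipped).
#' @return data.frame: `scheme`, `year`, `term`, `direct_estimate`,
#'   `total_lower`, `total_upper`, `flagged`, `interpretation`.
#' @export
comparison_flags <- function(tables) {
  dir <- tables[tables$family == "direct_linear" & tables$model == "linear" &
                  tables$term %in% c("leaf_out_day", "first_flowering_day"), ]
  tot <- tables[tables$family %in% c("total_leafout", "total_ffd") &
                  tables$model == "linear" &
                  tables$term %in% c("leaf_out_day", "first_flowering_day"), ]
  rows <- list()
  for (i in seq_len(nrow(dir))) {
    m <- tot[tot$term == dir$term[i] & tot$year == dir$year[i] &
               tot$scheme == dir$scheme[i], ]
    if (nrow(m) != 1 || is.na(m$bca_lower)) next
    cmp <- compare_direct_vs_total(dir[i, ], m)
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = dir$scheme[i], year = dir$year[i], term = dir$term[i],
      direct_estimate = dir$estimate[i],
      total_lower = m$bca_lower, total_upper = m$bca_upper,
      flagged = cmp$flagged, interpretation = cmp$interpretation,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(scheme = character(0), year = character(0), term = character(0),
                      direct_estimate = numeric(0), total_lower = numeric(0),
                      total_upper = numeric(0), flagged = logical(0),
                      interpretation = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
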