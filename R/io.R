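# CSV writers format doubles with "%.17g" so values round-trip exactly

format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      df[[j]] <- s
    }
  }
  df
}

write_csv_meta <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0) writeLines(paste0("# ", meta), con)
  utils::write.table(format_numeric_df(df), con, sep = ",", row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

meta_header <- function(seed = NULL, extra = character(0)) {
  v <- tryCatch(as.character(utils::packageVersion("trialcea")),
                error = function(e) "dev")
  c(sprintf("trialcea %s", v),
    if (!is.null(seed)) sprintf("seed %d", seed),
    extra)
}

# stable short hash of a configuration (FNV-1a over its deparsed form)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write a cohort to CSV
#'
#' One row per participant per recall window: the participant-level
#' columns (arm, covariates, ISI and utility measurements, completion
#' flags) repeated across that participant's windows, joined with the
#' window's resource-use quantities. Numeric values are written with
#' full double precision, so [read_cohort_csv()] reverses the write
#' losslessly.
#'
#' @param cohort an `ee_cohort`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ee_cohort"))
  merged <- merge(cohort$participants, cohort$resource_use, by = "id")
  merged <- merged[order(merged$id, merged$window), ]
  write_csv_meta(merged, path,
                 meta = meta_header(seed = cohort$params$seed,
                                    extra = sprintf("cohort n=%d windows=%d",
                                                    nrow(cohort$participants),
                                                    max(cohort$resource_use$window))))
  invisible(path)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param path CSV path.
#' @param params optional [cohort_params()] to re-attach (the CSV stores
#'   data, not generator parameters).
#' @return an `ee_cohort`.
#' @export
read_cohort_csv <- function(path, params = NULL) {
  merged <- read_csv_meta(path)
  part_cols <- c("id", "arm", "age", "baseline_depression",
                 "gross_daily_wage", "isi_t0", "isi_t1", "isi_t2",
                 "utility_t0", "utility_t1", "utility_t2",
                 "intervention_cost", "completed_followup", "missing_fields")
  ru_cols <- setdiff(names(merged), setdiff(part_cols, "id"))
  participants <- unique(merged[part_cols])
  participants <- participants[order(participants$id), ]
  rownames(participants) <- NULL
  participants$missing_fields[is.na(participants$missing_fields)] <- ""
  resource_use <- merged[ru_cols]
  resource_use <- resource_use[order(resource_use$id, resource_use$window), ]
  rownames(resource_use) <- NULL
  structure(list(participants = participants, resource_use = resource_use,
                 params = params),
            class = "ee_cohort")
}

#' Read a unit-cost table from a YAML configuration file
#'
#' Keys mirror the [unit_cost_table()] arguments; omitted keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a `unit_cost_table`.
#' @export
read_unit_cost_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (k in c("reference_year", "index_factor", "ppp_eur_to_gbp",
              "statutory_share", "intervention_price")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$prices)) args$prices <- unlist(cfg$prices)
  if (!is.null(cfg$medication_prices)) {
    args$medication_prices <- lapply(cfg$medication_prices, function(p) {
      if (is.list(p)) unlist(p) else p
    })
  }
  do.call(unit_cost_table, args)
}

#' Write a unit-cost table to YAML
#'
#' @param table a [unit_cost_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_unit_cost_config <- function(table, path) {
  stopifnot(inherits(table, "unit_cost_table"))
  yaml::write_yaml(list(
    reference_year = table$reference_year,
    index_factor = table$index_factor,
    ppp_eur_to_gbp = table$ppp_eur_to_gbp,
    statutory_share = table$statutory_share,
    intervention_price = table$intervention_price,
    prices = as.list(table$prices),
    medication_prices = lapply(table$medication_prices, function(p)
      if (length(p) > 1) as.list(p) else p)
  ), path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' Keys mirror the [scenario_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg),
                    c("id", "perspective", "outcome", "presenteeism_method",
                      "intervention_cost_multiplier", "sample", "impute",
                      "B", "seed", "lambdas", "level"))
  do.call(scenario_config, cfg[keep])
}

#' Write an evaluation result (or scenario matrix) to CSV
#'
#' A single `ee_result` is written as a one-row table with the same
#' columns as [run_matrix()] output; a matrix data.frame is written as
#' is. A commented metadata header records the package version, seed and
#' configuration hash.
#'
#' @param x an `ee_result` or a [run_matrix()] data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "ee_result")) {
    q <- attr(x$quadrants, "rounded")
    df <- data.frame(
      id = x$config$id, perspective = x$config$perspective,
      outcome = x$config$outcome,
      delta_cost = x$delta_cost,
      delta_cost_lo = x$delta_cost_ci[1], delta_cost_hi = x$delta_cost_ci[2],
      delta_effect = x$delta_effect,
      delta_effect_lo = x$delta_effect_ci[1],
      delta_effect_hi = x$delta_effect_ci[2],
      icer = ifelse(x$dominant, NA_real_, x$icer),
      icer_label = ifelse(x$dominant, "dominant", sprintf("%0.0f", x$icer)),
      icer_lo = x$icer_ci[1], icer_hi = x$icer_ci[2],
      pct_ne = q[["NE"]], pct_nw = q[["NW"]],
      pct_se = q[["SE"]], pct_sw = q[["SW"]],
      stringsAsFactors = FALSE)
    meta <- meta_header(seed = x$seed,
                        extra = sprintf("config %s", config_hash(x$config)))
  } else {
    df <- as.data.frame(x)
    meta <- meta_header()
  }
  write_csv_meta(df, path, meta)
  invisible(path)
}

#' Write a bootstrap cloud to CSV
#'
#' Replicate id and incremental cost/effect pair per row, for audit and
#' downstream decision analysis.
#'
#' @param cloud a `sur_cloud`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "sur_cloud"))
  df <- data.frame(replicate = seq_len(cloud$B), cloud$pairs)
  write_csv_meta(df, path, meta_header(seed = cloud$seed))
  invisible(path)
}

#' Write an acceptability curve to CSV
#'
#' @param curve data.frame from [ceac()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  write_csv_meta(curve, path, meta_header())
  invisible(path)
}
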