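# Configuration file handling. The entire parameter bundle, perspective
# definitions and run settings live in one versioned YAML document; the
# package ships the base case at
# system.file("extdata", "base_case.yaml", package = "decolcea").

config_schema <- list(
  top = c("config_version", "dollar_year", "population", "hob_risk",
          "treatment_effect", "adherence", "costs",
          "inflation_factor_2006_to_2022", "wtp", "options", "run"),
  population = c("p_device", "p_mrsa", "p_surgical"),
  hob_risk = c("device", "mrsa", "surgical", "events", "nonevents"),
  treatment_effect = c("hrr_treated", "hrr_untreated", "log_sd_treated",
                       "log_sd_untreated"),
  adherence = c("ud_chg", "ud_mupirocin", "td_relative", "soc_surgical_chg"),
  costs = c("excess_hob_payer_2006", "excess_hob_payer_ci_2006",
            "excess_hob_hospital", "chg_bed_bath_per_day", "chg_bed_bath_sd",
            "chg_shower_bottle", "chg_shower_bottle_sd",
            "std_bed_bath_per_day", "std_bed_bath_sd", "std_shower_per_day",
            "std_shower_sd", "mupirocin_course", "mupirocin_course_sd",
            "p_bed_bath", "los_mean", "los_iqr", "los_reported_sd"),
  wtp = c("payer", "hospital"),
  options = c("apply_untreated_hrr_under_soc"),
  run = c("psa_draws", "seed", "perspectives", "strategies", "out_dir")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop("unknown key `", unknown[1], "` in config section `", where, "`",
         call. = FALSE)
  }
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration carrying every model input (the shipped
#' default reproduces the base case), validates it against the documented
#' schema -- unknown keys are rejected by name, probabilities are range
#' checked -- and returns the parameter set plus run settings.
#'
#' @param path Path to a YAML configuration file; defaults to the shipped
#'   base-case configuration.
#' @return A list with `params` (a validated `decol_params`) and `run`
#'   (run settings: `psa_draws`, `seed`, `perspectives`, ...).
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$params$effect$hrr_treated
load_config <- function(path = system.file("extdata", "base_case.yaml",
                                           package = "decolcea")) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_schema$top, "<top level>")
  for (sec in c("population", "treatment_effect", "adherence", "costs",
                "wtp", "options", "run")) {
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], config_schema[[sec]], sec)
  }
  if (!identical(as.integer(raw$config_version), 1L)) {
    stop("unsupported config_version: ", raw$config_version, call. = FALSE)
  }
  if (!identical(as.integer(raw$dollar_year), 2022L)) {
    stop("config `dollar_year` must be 2022 (costs in other dollar-years ",
         "need an explicit inflation factor)", call. = FALSE)
  }
  if (length(raw$hob_risk) != 8L) {
    stop("config `hob_risk` must list all 8 strata", call. = FALSE)
  }

  risk <- decol_strata()
  key <- paste(risk$has_device, risk$mrsa_history, risk$surgical)
  ev <- ne <- rep(NA_real_, 8)
  for (row in raw$hob_risk) {
    check_keys(row, config_schema$hob_risk, "hob_risk")
    k <- paste(isTRUE(row$device), isTRUE(row$mrsa), isTRUE(row$surgical))
    i <- match(k, key)
    if (is.na(i)) stop("unrecognized stratum in `hob_risk`", call. = FALSE)
    ev[i] <- row$events; ne[i] <- row$nonevents
  }
  if (any(is.na(ev)) || any(is.na(ne))) {
    stop("config `hob_risk` is missing a stratum", call. = FALSE)
  }
  risk$events <- ev
  risk$nonevents <- ne
  risk$p_hob <- ev / (ev + ne)

  params <- list(
    risk = risk,
    effect = raw$treatment_effect,
    mix = raw$population,
    adherence = raw$adherence,
    costs = raw$costs[setdiff(names(raw$costs), "los_reported_sd")],
    inflation_factor_2006_to_2022 = raw$inflation_factor_2006_to_2022,
    wtp = raw$wtp,
    options = raw$options
  )
  params$costs$excess_hob_payer_ci_2006 <-
    as.numeric(params$costs$excess_hob_payer_ci_2006)
  params$costs$los_iqr <- as.numeric(params$costs$los_iqr)
  class(params) <- "decol_params"
  validate_params(params)

  run <- raw$run
  if (is.null(run)) run <- list()
  if (is.null(run$psa_draws)) run$psa_draws <- 10000L
  if (is.null(run$seed)) run$seed <- 1L
  if (is.null(run$perspectives)) run$perspectives <- c("payer", "hospital")
  if (is.null(run$strategies)) run$strategies <- c("SOC", "TD", "UD")
  list(params = params, run = run)
}

#' Serialize a parameter set back to the config format
#'
#' Writes YAML that [load_config()] reads back to a parameter set equal to
#' the input, value for value (17 significant digits, enough to round-trip
#' doubles exactly).
#'
#' @param params A `decol_params`.
#' @param path Output path.
#' @param run Optional run-settings list to embed.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, run = NULL) {
  validate_params(params)
  r <- params$risk
  doc <- list(
    config_version = 1L,
    dollar_year = 2022L,
    population = params$mix,
    hob_risk = lapply(seq_len(8), function(i) {
      list(device = r$has_device[i], mrsa = r$mrsa_history[i],
           surgical = r$surgical[i], events = r$events[i],
           nonevents = r$nonevents[i])
    }),
    treatment_effect = params$effect,
    adherence = params$adherence,
    costs = params$costs,
    inflation_factor_2006_to_2022 = params$inflation_factor_2006_to_2022,
    wtp = params$wtp,
    options = params$options
  )
  if (!is.null(run)) doc$run <- run
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Emits stable CSV schemas (one value per cell, costs in full-precision
#' 2022 US$), a strategy-ranking table shaped like the published
#' cost-effectiveness table, and a run-metadata JSON (seed, draw count,
#' package version, config hash). Rounding to display precision happens
#' only in printed summaries, never in the CSVs.
#'
#' @param psa A `decol_psa` from [run_psa()].
#' @param out_dir Output directory (created if needed).
#' @param params The `decol_params` evaluated (for the ranking table).
#' @param config_path Optional path of the config used, hashed into the
#'   metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(psa, out_dir, params = NULL, config_path = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(psa$summary, "psa_summary.csv")
  wr(psa$incremental, "psa_incremental.csv")
  wr(psa$prob_optimal, "psa_prob_optimal.csv")
  if (!is.null(psa$draws)) wr(psa$draws, "psa_draws.csv")

  if (!is.null(params)) {
    rank_rows <- lapply(unique(psa$summary$perspective), function(pvn) {
      pv <- perspectives(params, pvn)[[1]]
      sp <- psa$summary[psa$summary$perspective == pvn, ]
      cea <- rank_and_icer(data.frame(strategy = sp$strategy,
                                      hob_per_1000 = sp$hob_mean,
                                      total_cost_per_1000 = sp$cost_mean),
                           pv$wtp)
      tab <- cea$table
      tab$perspective <- pvn
      tab$optimal <- tab$strategy == cea$optimal
      tab
    })
    wr(do.call(rbind, rank_rows), "strategy_ranking.csv")
  }

  meta <- list(
    package = "decolcea",
    version = as.character(utils::packageVersion("decolcea")),
    seed = psa$seed, n_draws = psa$n_draws,
    config_md5 = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    }
  )
  mf <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, null = "null")
  files <- c(files, mf)
  invisible(files)
}
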