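#' Patient-level microsimulation of a cohort under one strategy
#'
#' Independent oracle for the cohort expectations: simulates individual
#' admissions with exactly the statistical structure the decision tree
#' assumes. Patient attributes (device, MRSA history, surgical) are drawn
#' as independent Bernoulli variables from the population mix; receipt of
#' chlorhexidine bathing and mupirocin are Bernoulli per the strategy's
#' stratum rules; HOB is Bernoulli with the stratum baseline probability
#' scaled by the received (treated/untreated) hazard rate ratio for
#' device patients; length of stay is drawn per patient from the fitted
#' log-normal; bed-bath vs shower assignment is Bernoulli and fixed for
#' the stay. Costs accumulate per the decision-model rules, so empirical
#' means must agree with the analytic expectations (the analytic model
#' uses the mean length of stay, which matches because costs are linear
#' in length of stay).
#'
#' Scaled HOB probabilities above 1 are capped with a warning (cannot
#' occur at base-case values).
#'
#' @param n_patients Number of simulated admissions.
#' @param strategy A `decol_strategy`.
#' @param params A `decol_params`.
#' @param perspective One element of [perspectives()].
#' @param seed Integer seed.
#' @param keep_patients Return the per-patient table?
#' @return A `decol_sim` list: `outcomes` (empirical per-1000 rates:
#'   `hob_per_1000`, `upstream_cost_per_1000`, `downstream_cost_per_1000`,
#'   `total_cost_per_1000`, `mupirocin_treated_per_1000`), `se` (matching
#'   Monte Carlo standard errors), `stratum_counts`, `n_patients`, `seed`,
#'   and optionally `patients`.
#' @export
#' @examples
#' p <- build_base_case()
#' sim <- simulate_cohort(20000, strategy_set(p)$UD, p,
#'                        perspectives(p)$payer, seed = 7)
#' sim$outcomes$hob_per_1000
simulate_cohort <- function(n_patients, strategy, params, perspective,
                            seed = 1, keep_patients = FALSE) {
  stopifnot(n_patients >= 1)
  check_strategy(strategy)
  set.seed(seed)
  s <- decol_strata()
  mix <- params$mix
  cs <- params$costs

  device <- stats::runif(n_patients) < mix$p_device
  mrsa <- stats::runif(n_patients) < mix$p_mrsa
  surgical <- stats::runif(n_patients) < mix$p_surgical
  # stratum index in decol_strata() order
  idx <- 1L + 4L * (!device) + 2L * (!mrsa) + (!surgical)

  chg <- stats::runif(n_patients) < strategy$chg[idx]
  mup <- stats::runif(n_patients) < strategy$mupirocin[idx]

  hu <- params$effect$hrr_untreated
  if (identical(strategy$name, "SOC") &&
      !isTRUE(params$options$apply_untreated_hrr_under_soc)) {
    hu <- 1
  }
  mult <- ifelse(device, ifelse(chg, params$effect$hrr_treated, hu), 1)
  p_hob <- params$risk$p_hob[idx] * mult
  if (any(p_hob > 1)) {
    warning(sum(p_hob > 1), " scaled HOB probabilities exceeded 1 and were capped")
    p_hob <- pmin(p_hob, 1)
  }
  hob <- stats::runif(n_patients) < p_hob

  lf <- lognormal_from_mean_iqr(cs$los_mean, cs$los_iqr[1], cs$los_iqr[2])
  los <- stats::rlnorm(n_patients, lf$meanlog, lf$sdlog)
  bed_bath <- stats::runif(n_patients) < cs$p_bed_bath
  daily <- ifelse(chg,
                  ifelse(bed_bath, cs$chg_bed_bath_per_day,
                         cs$chg_shower_bottle / 2),
                  ifelse(bed_bath, cs$std_bed_bath_per_day,
                         cs$std_shower_per_day))
  upstream <- daily * los + ifelse(mup, cs$mupirocin_course, 0)
  downstream <- ifelse(hob, perspective$excess_hob_cost, 0)

  per1000 <- function(x) 1000 * mean(x)
  se1000 <- function(x) 1000 * stats::sd(x) / sqrt(n_patients)
  total <- upstream + downstream
  out <- list(
    outcomes = list(
      hob_per_1000 = per1000(hob),
      upstream_cost_per_1000 = per1000(upstream),
      downstream_cost_per_1000 = per1000(downstream),
      total_cost_per_1000 = per1000(total),
      mupirocin_treated_per_1000 = per1000(mup)
    ),
    se = list(
      hob_per_1000 = se1000(hob),
      upstream_cost_per_1000 = se1000(upstream),
      downstream_cost_per_1000 = se1000(downstream),
      total_cost_per_1000 = se1000(total),
      mupirocin_treated_per_1000 = se1000(mup)
    ),
    stratum_counts = tabulate(idx, nbins = 8L),
    strategy = strategy$name, perspective = perspective$name,
    n_patients = n_patients, seed = seed
  )
  if (keep_patients) {
    out$patients <- data.frame(
      stratum = s$label[idx], has_device = device, mrsa_history = mrsa,
      surgical = surgical, received_chg = chg, received_mupirocin = mup,
      los_days = los, hob_event = hob, upstream_cost = upstream,
      downstream_cost = downstream
    )
  }
  class(out) <- "decol_sim"
  out
}

#' Validate the decision tree against the microsimulation
#'
#' Runs [simulate_cohort()] for every strategy and perspective and checks
#' that each empirical outcome lies within `z` Monte Carlo standard errors
#' of its analytic expectation from [evaluate_strategy()].
#'
#' @param params A `decol_params`.
#' @param n_patients Simulated admissions per strategy (default 1e6).
#' @param seed Integer seed.
#' @param z Tolerance in standard errors (default 3).
#' @return A `decol_validation` data frame with one row per strategy x
#'   perspective x outcome: analytic value, empirical value, standard
#'   error, z-score, and pass flag; attribute `all_pass`.
#' @export
validate_model <- function(params = build_base_case(), n_patients = 1e6,
                           seed = 1, z = 3) {
  strategies <- strategy_set(params)
  persp <- perspectives(params)
  fields <- c("hob_per_1000", "upstream_cost_per_1000",
              "downstream_cost_per_1000", "total_cost_per_1000",
              "mupirocin_treated_per_1000")
  rows <- list()
  for (st in strategies) {
    for (pv in persp) {
      # one simulated cohort per strategy/perspective pair, distinct seeds
      sim <- simulate_cohort(n_patients, st, params, pv,
                             seed = seed + 101L * match(st$name, names(strategies)) +
                               7L * match(pv$name, names(persp)))
      ana <- evaluate_strategy(st, params, pv)
      for (f in fields) {
        se <- max(sim$se[[f]], .Machine$double.eps)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = st$name, perspective = pv$name, outcome = f,
          analytic = ana[[f]], empirical = sim$outcomes[[f]], se = se,
          z = (sim$outcomes[[f]] - ana[[f]]) / se
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$pass <- abs(out$z) < z
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  class(out) <- c("decol_validation", class(out))
  out
}

#' @export
print.decol_validation <- function(x, ...) {
  df <- as.data.frame(x)
  df$analytic <- signif(df$analytic, 6)
  df$empirical <- signif(df$empirical, 6)
  df$se <- signif(df$se, 3)
  df$z <- round(df$z, 2)
  print(df, row.names = FALSE)
  cat(if (isTRUE(attr(x, "all_pass"))) "All outcomes within tolerance.\n"
      else "SOME OUTCOMES OUTSIDE TOLERANCE.\n")
  invisible(x)
}
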