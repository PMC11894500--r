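# Core cohort evaluators. Each evaluator has a scalar user-facing form and
# a vectorized internal form used by the PSA, where per-draw parameter
# values are supplied as equal-length vectors (or an n x 8 matrix for the
# stratum risks). All outcomes are expectations per admission scaled to
# 1000 admissions; expected counts are never rounded.

# Per-stratum effect multiplier on the baseline HOB probability.
# HRRs are scoped to device strata only; non-device strata always carry 1.
# Under SOC the convention for unbathed device patients is controlled by
# `apply_untreated_hrr_under_soc` (TRUE: they carry hrr_untreated, i.e. the
# decision-tree baseline is the trial's baseline period; FALSE: 1.0).
effect_multiplier <- function(strategy, params, hrr_treated = NULL,
                              hrr_untreated = NULL) {
  check_strategy(strategy)
  s <- decol_strata()
  ht <- if (is.null(hrr_treated)) params$effect$hrr_treated else hrr_treated
  hu <- if (is.null(hrr_untreated)) params$effect$hrr_untreated else hrr_untreated
  if (identical(strategy$name, "SOC") &&
      !isTRUE(params$options$apply_untreated_hrr_under_soc)) {
    hu <- 1
  }
  # outer structure: length(ht) draws x 8 strata
  mult <- matrix(1, nrow = length(ht), ncol = 8L)
  for (j in which(s$has_device)) {
    mult[, j] <- strategy$chg[j] * ht + (1 - strategy$chg[j]) * hu
  }
  mult
}

#' Expected HOB events per 1000 admissions
#'
#' Population-weighted sum of stratum HOB probabilities times the
#' strategy's treatment-effect multiplier. For device strata the
#' multiplier mixes the treated and untreated hazard rate ratios by the
#' stratum's CHG receipt probability; non-device strata are unaffected by
#' treatment (the trial effect estimate is scoped to patients with
#' devices).
#'
#' @param strategy A `decol_strategy` (see [strategy_set()]).
#' @param params A `decol_params` object.
#' @return Expected HOB events per 1000 admissions.
#' @export
#' @examples
#' p <- build_base_case()
#' expected_hob(strategy_set(p)$SOC, p)
expected_hob <- function(strategy, params) {
  w <- stratum_weights(params$mix)
  mult <- effect_multiplier(strategy, params)
  1000 * sum(w * params$risk$p_hob * mult[1, ])
}

# Vectorized over draws: p_hob an n x 8 matrix, ht/hu length-n vectors.
expected_hob_draws <- function(strategy, params, p_hob, ht, hu) {
  w <- stratum_weights(params$mix)
  mult <- effect_multiplier(strategy, params, ht, hu)
  1000 * as.vector((p_hob * mult) %*% w)
}

# Expected daily bathing product cost per patient given a CHG receipt
# probability; bed baths and showers mix at p_bed_bath. The CHG shower
# bottle lasts two days, so its per-day cost is half the bottle cost.
daily_bathing_cost <- function(chg_prob, costs, chg_bed = NULL,
                               chg_bottle = NULL, std_bed = NULL,
                               std_shower = NULL) {
  pbb <- costs$p_bed_bath
  if (is.null(chg_bed)) chg_bed <- costs$chg_bed_bath_per_day
  if (is.null(chg_bottle)) chg_bottle <- costs$chg_shower_bottle
  if (is.null(std_bed)) std_bed <- costs$std_bed_bath_per_day
  if (is.null(std_shower)) std_shower <- costs$std_shower_per_day
  chg_daily <- pbb * chg_bed + (1 - pbb) * chg_bottle / 2
  std_daily <- pbb * std_bed + (1 - pbb) * std_shower
  chg_prob * chg_daily + (1 - chg_prob) * std_daily
}

#' Upstream (intervention) cost per 1000 admissions
#'
#' Daily bathing product cost (bed-bath/shower mixture, chlorhexidine vs
#' standard soap by the stratum's CHG probability) over the expected
#' length of stay, plus the mupirocin course cost times the stratum's
#' mupirocin probability, weighted over strata.
#'
#' @inheritParams expected_hob
#' @return Upstream cost (2022 US$) per 1000 admissions.
#' @export
upstream_cost <- function(strategy, params) {
  check_strategy(strategy)
  w <- stratum_weights(params$mix)
  daily <- daily_bathing_cost(strategy$chg, params$costs)
  1000 * sum(w * (daily * params$costs$los_mean +
                    strategy$mupirocin * params$costs$mupirocin_course))
}

upstream_cost_draws <- function(strategy, params, los, chg_bed, chg_bottle,
                                std_bed, std_shower, mup_course) {
  w <- stratum_weights(params$mix)
  wchg <- sum(w * strategy$chg)
  wmup <- sum(w * strategy$mupirocin)
  pbb <- params$costs$p_bed_bath
  chg_daily <- pbb * chg_bed + (1 - pbb) * chg_bottle / 2
  std_daily <- pbb * std_bed + (1 - pbb) * std_shower
  1000 * (los * (wchg * chg_daily + (1 - wchg) * std_daily) +
            mup_course * wmup)
}

#' Patients receiving mupirocin per 1000 admissions
#'
#' @inheritParams expected_hob
#' @return Expected mupirocin recipients per 1000 admissions (unrounded).
#' @export
#' @examples
#' p <- build_base_case()
#' mupirocin_treated(strategy_set(p)$UD, p)  # 1000 x 0.08 x 0.88 = 70.4
mupirocin_treated <- function(strategy, params) {
  check_strategy(strategy)
  1000 * sum(stratum_weights(params$mix) * strategy$mupirocin)
}

#' Evaluate a strategy's outcomes under a perspective
#'
#' @inheritParams expected_hob
#' @param perspective One element of [perspectives()] (carries the excess
#'   cost per HOB event and the willingness-to-pay threshold).
#' @return A `decol_outcomes` list: `strategy`, `perspective`,
#'   `hob_per_1000`, `upstream_cost_per_1000`, `downstream_cost_per_1000`,
#'   `total_cost_per_1000` (= upstream + downstream, exactly), and
#'   `mupirocin_treated_per_1000`.
#' @export
#' @examples
#' p <- build_base_case()
#' evaluate_strategy(strategy_set(p)$TD, p, perspectives(p)$hospital)
evaluate_strategy <- function(strategy, params, perspective) {
  hob <- expected_hob(strategy, params)
  up <- upstream_cost(strategy, params)
  down <- hob * perspective$excess_hob_cost
  structure(list(
    strategy = strategy$name,
    perspective = perspective$name,
    hob_per_1000 = hob,
    upstream_cost_per_1000 = up,
    downstream_cost_per_1000 = down,
    total_cost_per_1000 = up + down,
    mupirocin_treated_per_1000 = mupirocin_treated(strategy, params)
  ), class = "decol_outcomes")
}

#' Base-case evaluation of all strategies and perspectives
#'
#' Point (non-probabilistic) evaluation of the decision tree with every
#' distribution collapsed to its point value; deterministic.
#'
#' @param params A `decol_params` object.
#' @param which_perspectives Perspectives to evaluate.
#' @return A data frame with one row per strategy x perspective.
#' @export
run_base_case <- function(params = build_base_case(),
                          which_perspectives = c("payer", "hospital")) {
  strategies <- strategy_set(params)
  persp <- perspectives(params, which_perspectives)
  rows <- lapply(persp, function(pv) {
    do.call(rbind, lapply(strategies, function(st) {
      o <- evaluate_strategy(st, params, pv)
      data.frame(
        strategy = o$strategy, perspective = o$perspective,
        hob_per_1000 = o$hob_per_1000,
        upstream_cost_per_1000 = o$upstream_cost_per_1000,
        downstream_cost_per_1000 = o$downstream_cost_per_1000,
        total_cost_per_1000 = o$total_cost_per_1000,
        mupirocin_treated_per_1000 = o$mupirocin_treated_per_1000
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.decol_outcomes <- function(x, ...) {
  cat(sprintf("%s (%s perspective), per 1000 admissions:\n",
              x$strategy, x$perspective))
  cat(sprintf("  HOB events        %8.2f\n", x$hob_per_1000))
  cat(sprintf("  upstream cost     $%10.0f\n", x$upstream_cost_per_1000))
  cat(sprintf("  downstream cost   $%10.0f\n", x$downstream_cost_per_1000))
  cat(sprintf("  total cost        $%10.0f\n", x$total_cost_per_1000))
  cat(sprintf("  mupirocin treated %8.1f\n", x$mupirocin_treated_per_1000))
  invisible(x)
}
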