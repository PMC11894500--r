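# Probabilistic sensitivity analysis.
#
# One RNG stream per run. Within a run, parameter blocks are drawn in a
# fixed documented order so that adding a parameter at the end of the list
# never perturbs earlier draws:
#   1. stratum HOB risks, beta(events, nonevents), strata in decol_strata()
#      order (all draws for stratum 1, then stratum 2, ...);
#   2. log-normal HRRs: treated, then untreated (meanlog = log point HRR,
#      sdlog as reported);
#   3. gamma unit costs: CHG bed bath, CHG shower bottle, standard bed
#      bath, standard shower soap, mupirocin course;
#   4. truncated-normal payer excess-HOB cost on the 2006 scale (resampled
#      while negative, bounded retries), inflated to 2022 after sampling;
#   5. log-normal length of stay (arithmetic mean 6.5 d matched to IQR 4-8).
# "Fixed" parameters (population mix, adherence, bed-bath proportion,
# hospital excess-HOB cost, WTP) are copied unchanged.

sample_parameter_draws <- function(params, n, uncertainty_scale = 1) {
  stopifnot(n >= 1, uncertainty_scale >= 0)
  cs <- params$costs
  ef <- params$effect
  s <- uncertainty_scale

  if (s == 0) {
    ppay <- inflate_cost(cs$excess_hob_payer_2006,
                         params$inflation_factor_2006_to_2022)
    return(list(
      p_hob = matrix(rep(params$risk$p_hob, each = n), nrow = n),
      hrr_treated = rep(ef$hrr_treated, n),
      hrr_untreated = rep(ef$hrr_untreated, n),
      chg_bed = rep(cs$chg_bed_bath_per_day, n),
      chg_bottle = rep(cs$chg_shower_bottle, n),
      std_bed = rep(cs$std_bed_bath_per_day, n),
      std_shower = rep(cs$std_shower_per_day, n),
      mup_course = rep(cs$mupirocin_course, n),
      excess_payer = rep(ppay, n),
      los = rep(cs$los_mean, n)
    ))
  }

  # beta counts scaled by 1/s^2 so the sd scales by ~s while the mean is kept
  p_hob <- vapply(seq_len(8), function(j) {
    stats::rbeta(n, params$risk$events[j] / s^2, params$risk$nonevents[j] / s^2)
  }, numeric(n))
  if (n == 1L) p_hob <- matrix(p_hob, nrow = 1L)

  hrr_treated <- stats::rlnorm(n, log(ef$hrr_treated), s * ef$log_sd_treated)
  hrr_untreated <- stats::rlnorm(n, log(ef$hrr_untreated),
                                 s * ef$log_sd_untreated)

  rgam <- function(mean, sd) {
    g <- gamma_from_mean_sd(mean, s * sd)
    stats::rgamma(n, shape = g$shape, scale = g$scale)
  }
  chg_bed <- rgam(cs$chg_bed_bath_per_day, cs$chg_bed_bath_sd)
  chg_bottle <- rgam(cs$chg_shower_bottle, cs$chg_shower_bottle_sd)
  std_bed <- rgam(cs$std_bed_bath_per_day, cs$std_bed_bath_sd)
  std_shower <- rgam(cs$std_shower_per_day, cs$std_shower_sd)
  mup_course <- rgam(cs$mupirocin_course, cs$mupirocin_course_sd)

  ci <- cs$excess_hob_payer_ci_2006
  sd06 <- s * (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  excess06 <- stats::rnorm(n, cs$excess_hob_payer_2006, sd06)
  for (tries in seq_len(100)) {
    neg <- excess06 < 0
    if (!any(neg)) break
    excess06[neg] <- stats::rnorm(sum(neg), cs$excess_hob_payer_2006, sd06)
  }
  if (any(excess06 < 0)) {
    stop("payer excess-HOB cost truncation failed after bounded retries",
         call. = FALSE)
  }
  excess_payer <- inflate_cost(excess06, params$inflation_factor_2006_to_2022)

  lf <- lognormal_from_mean_iqr(cs$los_mean, cs$los_iqr[1], cs$los_iqr[2])
  sdlog <- s * lf$sdlog
  los <- stats::rlnorm(n, log(cs$los_mean) - sdlog^2 / 2, sdlog)

  list(p_hob = p_hob, hrr_treated = hrr_treated,
       hrr_untreated = hrr_untreated, chg_bed = chg_bed,
       chg_bottle = chg_bottle, std_bed = std_bed, std_shower = std_shower,
       mup_course = mup_course, excess_payer = excess_payer, los = los)
}

#' Draw one sampled parameter set
#'
#' Samples every uncertain parameter from its probabilistic-sensitivity
#' distribution (beta stratum risks, log-normal HRRs, gamma unit costs,
#' truncated-normal payer excess-HOB cost, log-normal length of stay) and
#' returns a parameter set with the draws substituted; fixed rows are
#' copied unchanged. Uses the current RNG state.
#'
#' @param params Base `decol_params`.
#' @return A `decol_params` with sampled values. The sampled 2022-dollar
#'   payer cost is stored by back-scaling to 2006 dollars so that
#'   [perspectives()] reproduces it.
#' @export
sample_parameters <- function(params) {
  d <- sample_parameter_draws(params, 1L)
  out <- params
  out$risk$p_hob <- as.vector(d$p_hob)
  out$effect$hrr_treated <- d$hrr_treated
  out$effect$hrr_untreated <- d$hrr_untreated
  out$costs$chg_bed_bath_per_day <- d$chg_bed
  out$costs$chg_shower_bottle <- d$chg_bottle
  out$costs$std_bed_bath_per_day <- d$std_bed
  out$costs$std_shower_per_day <- d$std_shower
  out$costs$mupirocin_course <- d$mup_course
  out$costs$excess_hob_payer_2006 <-
    d$excess_payer / params$inflation_factor_2006_to_2022
  out$costs$los_mean <- d$los
  out
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter sets, evaluates every strategy under every
#' perspective for each draw, and summarizes the draws: means as point
#' estimates and 2.5th/97.5th centiles as 95% uncertainty intervals.
#' Incremental UD-vs-TD quantities are computed pairwise within draws.
#' ICERs are ratios of mean incremental cost to mean incremental effect
#' (average ICERs), not means of per-draw ratios. The probability that
#' each strategy is optimal applies the frontier/willingness-to-pay rule
#' of [rank_and_icer()] draw by draw.
#'
#' @param params Base `decol_params`.
#' @param n_draws Number of parameter draws (default 10000).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param which_perspectives Perspectives to evaluate.
#' @param keep_draws Keep the per-draw table? (`draws` element).
#' @param uncertainty_scale Multiplier on every distribution's spread
#'   (1 = as specified; 0 collapses to the deterministic base case).
#' @return A `decol_psa` list with `summary` (per strategy x perspective:
#'   mean and UI of HOB and total cost), `incremental` (UD vs TD per
#'   perspective: HOB averted, cost difference, average ICER),
#'   `prob_optimal`, `mupirocin_treated`, `n_draws`, `seed`, and
#'   optionally `draws`.
#' @export
#' @examples
#' psa <- run_psa(build_base_case(), n_draws = 500, seed = 1)
#' psa
run_psa <- function(params, n_draws = 10000, seed = 1,
                    which_perspectives = c("payer", "hospital"),
                    keep_draws = FALSE, uncertainty_scale = 1) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  d <- sample_parameter_draws(params, n_draws, uncertainty_scale)
  strategies <- strategy_set(params)
  persp <- perspectives(params, which_perspectives)

  hob <- lapply(strategies, function(st) {
    expected_hob_draws(st, params, d$p_hob, d$hrr_treated, d$hrr_untreated)
  })
  up <- lapply(strategies, function(st) {
    upstream_cost_draws(st, params, d$los, d$chg_bed, d$chg_bottle,
                        d$std_bed, d$std_shower, d$mup_course)
  })
  excess <- list(payer = d$excess_payer,
                 hospital = rep(params$costs$excess_hob_hospital, n_draws))
  total <- lapply(persp, function(pv) {
    lapply(names(strategies), function(nm) up[[nm]] + hob[[nm]] * excess[[pv$name]])
  })
  for (pv in names(total)) names(total[[pv]]) <- names(strategies)

  ui <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- do.call(rbind, lapply(persp, function(pv) {
    do.call(rbind, lapply(names(strategies), function(nm) {
      h <- hob[[nm]]; tc <- total[[pv$name]][[nm]]
      data.frame(
        strategy = nm, perspective = pv$name,
        hob_mean = mean(h), hob_lo = ui(h)[1], hob_hi = ui(h)[2],
        cost_mean = mean(tc), cost_lo = ui(tc)[1], cost_hi = ui(tc)[2]
      )
    }))
  }))
  rownames(summ) <- NULL

  d_hob <- hob$TD - hob$UD  # HOB events averted by UD relative to TD
  incr <- do.call(rbind, lapply(persp, function(pv) {
    d_cost <- total[[pv$name]]$UD - total[[pv$name]]$TD
    data.frame(
      perspective = pv$name,
      hob_averted_mean = mean(d_hob),
      hob_averted_lo = ui(d_hob)[1], hob_averted_hi = ui(d_hob)[2],
      cost_diff_mean = mean(d_cost),
      cost_diff_lo = ui(d_cost)[1], cost_diff_hi = ui(d_cost)[2],
      icer = mean(d_cost) / mean(d_hob)
    )
  }))
  rownames(incr) <- NULL

  prob_opt <- do.call(rbind, lapply(persp, function(pv) {
    wins <- vapply(seq_len(n_draws), function(i) {
      cost_i <- vapply(names(strategies),
                       function(nm) total[[pv$name]][[nm]][i], 0)
      hob_i <- vapply(names(strategies), function(nm) hob[[nm]][i], 0)
      ord <- order(cost_i, hob_i, names(strategies))
      fr <- frontier_core(cost_i[ord], hob_i[ord], pv$wtp)
      names(strategies)[ord][fr$opt]
    }, "")
    data.frame(perspective = pv$name,
               strategy = names(strategies),
               prob_optimal = vapply(names(strategies),
                                     function(nm) mean(wins == nm), 0),
               row.names = NULL)
  }))
  rownames(prob_opt) <- NULL

  out <- list(
    summary = summ, incremental = incr, prob_optimal = prob_opt,
    mupirocin_treated = vapply(strategies,
                               function(st) mupirocin_treated(st, params), 0),
    n_draws = n_draws, seed = seed
  )
  if (keep_draws) {
    out$draws <- data.frame(
      draw = rep(seq_len(n_draws), times = length(persp) * 3),
      perspective = rep(vapply(persp, `[[`, "", "name"),
                        each = n_draws * 3),
      strategy = rep(rep(names(strategies), each = n_draws),
                     times = length(persp)),
      hob_per_1000 = unlist(lapply(persp, function(pv) unlist(hob)),
                            use.names = FALSE),
      total_cost_per_1000 = unlist(lapply(persp, function(pv) {
        unlist(total[[pv$name]])
      }), use.names = FALSE)
    )
  }
  class(out) <- "decol_psa"
  out
}

#' @export
print.decol_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d)\n", x$n_draws, x$seed))
  s <- x$summary
  for (pv in unique(s$perspective)) {
    cat(sprintf("\n%s perspective, per 1000 admissions:\n", pv))
    sp <- s[s$perspective == pv, ]
    for (i in seq_len(nrow(sp))) {
      cat(sprintf("  %-4s HOB %.1f (%.1f-%.1f)   total cost $%s ($%s-$%s)\n",
                  sp$strategy[i], sp$hob_mean[i], sp$hob_lo[i], sp$hob_hi[i],
                  format(round(sp$cost_mean[i]), big.mark = ","),
                  format(round(sp$cost_lo[i]), big.mark = ","),
                  format(round(sp$cost_hi[i]), big.mark = ",")))
    }
    inc <- x$incremental[x$incremental$perspective == pv, ]
    cat(sprintf("  UD vs TD: %.3f HOB averted (%.3f-%.3f), cost +$%s (%s-%s), ICER $%s\n",
                inc$hob_averted_mean, inc$hob_averted_lo, inc$hob_averted_hi,
                format(round(inc$cost_diff_mean), big.mark = ","),
                format(round(inc$cost_diff_lo), big.mark = ","),
                format(round(inc$cost_diff_hi), big.mark = ","),
                format(round(inc$icer), big.mark = ",")))
  }
  invisible(x)
}
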