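#' Rank strategies, apply dominance, compute ICERs, pick the optimum
#'
#' Implements the conventional cost-effectiveness ranking: strategies are
#' ordered by increasing total cost (ties broken by fewer HOB events);
#' strongly dominated strategies (at least as many HOB events at higher
#' cost, or more events at equal-or-higher cost) are removed first, then
#' extendedly dominated ones (those bypassed by the efficient frontier,
#' detected as a non-increasing ICER sequence). ICERs are computed for
#' each remaining strategy against the next cheapest remaining one, as
#' incremental cost divided by HOB events averted. The optimal strategy
#' is the one with the highest ICER at or below the willingness-to-pay
#' threshold; when no ICER qualifies it is the cheapest undominated
#' strategy.
#'
#' A costlier strategy averting exactly zero additional events is
#' dominated (no division by zero arises); exact duplicates collapse onto
#' the first-ordered copy.
#'
#' @param outcomes A data frame with columns `strategy`, `hob_per_1000`,
#'   `total_cost_per_1000` (one row per strategy), or a list of
#'   `decol_outcomes`.
#' @param wtp Willingness-to-pay threshold, US$ per HOB event averted.
#' @return A `decol_cea` list: `table` (cost-ordered data frame with
#'   `strategy`, `hob_per_1000`, `total_cost_per_1000`, `dominance`,
#'   `icer`), `optimal` (strategy name), and `wtp`. ICERs are `NA` for
#'   dominated strategies and for the cheapest undominated (baseline)
#'   strategy.
#' @export
#' @examples
#' p <- build_base_case()
#' rank_and_icer(run_base_case(p, "payer"), wtp = 25000)
rank_and_icer <- function(outcomes, wtp) {
  if (inherits(outcomes, "decol_outcomes")) outcomes <- list(outcomes)
  if (is.list(outcomes) && !is.data.frame(outcomes)) {
    outcomes <- do.call(rbind, lapply(outcomes, function(o) {
      data.frame(strategy = o$strategy, hob_per_1000 = o$hob_per_1000,
                 total_cost_per_1000 = o$total_cost_per_1000)
    }))
  }
  need <- c("strategy", "hob_per_1000", "total_cost_per_1000")
  if (!all(need %in% names(outcomes))) {
    stop("`outcomes` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(outcomes) < 1L) stop("at least one strategy is required",
                                call. = FALSE)
  if (any(!is.finite(outcomes$hob_per_1000)) ||
      any(!is.finite(outcomes$total_cost_per_1000))) {
    stop("outcomes must be finite", call. = FALSE)
  }
  if (!is.numeric(wtp) || length(wtp) != 1L || !is.finite(wtp) || wtp < 0) {
    stop("`wtp` must be a nonnegative number", call. = FALSE)
  }

  tab <- outcomes[order(outcomes$total_cost_per_1000, outcomes$hob_per_1000,
                        outcomes$strategy), need, drop = FALSE]
  rownames(tab) <- NULL
  fr <- frontier_core(tab$total_cost_per_1000, tab$hob_per_1000, wtp)
  tab$dominance <- fr$dominance
  tab$icer <- fr$icer
  structure(list(table = tab, optimal = tab$strategy[fr$opt], wtp = wtp),
            class = "decol_cea")
}

# Frontier algorithm on cost-ordered vectors (nondecreasing cost; ties
# already broken by fewer HOB events). Returns dominance labels, ICERs
# along the undominated frontier, and the index of the optimum at `wtp`.
frontier_core <- function(cost, hob, wtp) {
  n <- length(cost)
  dominance <- rep("undominated", n)

  # strong (simple) dominance, including the weak boundary cases
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- (cost[j] <= cost[i] && hob[j] < hob[i]) ||
        (cost[j] < cost[i] && hob[j] <= hob[i]) ||
        (cost[j] == cost[i] && hob[j] == hob[i] && j < i)  # duplicate
      if (better) {
        dominance[i] <- "strongly_dominated"
        break
      }
    }
  }

  # extended dominance: enforce strictly increasing ICERs along the frontier
  repeat {
    alive <- which(dominance == "undominated")
    if (length(alive) < 3L) break
    icers <- diff(cost[alive]) / -diff(hob[alive])
    bad <- which(diff(icers) <= 0)
    if (length(bad) == 0L) break
    dominance[alive[bad[1] + 1L]] <- "extendedly_dominated"
  }

  alive <- which(dominance == "undominated")
  icer <- rep(NA_real_, n)
  if (length(alive) > 1L) {
    icer[alive[-1]] <- diff(cost[alive]) / -diff(hob[alive])
  }

  # highest ICER at or below WTP; the cheapest undominated strategy
  # (no ICER) is the fallback
  opt <- alive[1]
  for (k in alive[-1]) if (icer[k] <= wtp) opt <- k
  list(dominance = dominance, icer = icer, opt = opt)
}

#' @export
print.decol_cea <- function(x, ...) {
  tab <- x$table
  tab$total_cost_per_1000 <- round(tab$total_cost_per_1000)
  tab$hob_per_1000 <- round(tab$hob_per_1000, 2)
  tab$icer <- round(tab$icer)
  print(tab, row.names = FALSE)
  cat(sprintf("Optimal at WTP $%s per HOB averted: %s\n",
              format(x$wtp, big.mark = ","), x$optimal))
  invisible(x)
}
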