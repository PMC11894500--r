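# Deterministic sensitivity analyses: one-way curves, the multi-way
# optimal-strategy grid, and the hospital HOB-cost threshold scatter.

dsa_parameters <- c("p_device", "p_mrsa", "p_surgical", "hrr_reduction",
                    "wtp", "td_relative_adherence", "td_absolute_adherence",
                    "excess_hob_hospital")

# Returns modified (params, wtp_override) for one grid value.
apply_dsa_value <- function(params, name, value) {
  wtp_override <- NULL
  switch(name,
    p_device = { params$mix$p_device <- value },
    p_mrsa = { params$mix$p_mrsa <- value },
    p_surgical = { params$mix$p_surgical <- value },
    # reduction r in the hazard rate ratio among device patients who
    # received decolonization: hrr_treated = 1 - r, untreated held at base
    hrr_reduction = { params$effect$hrr_treated <- 1 - value },
    wtp = { wtp_override <- value },
    td_relative_adherence = { params$adherence$td_relative <- value },
    td_absolute_adherence = {
      params$adherence$td_relative <- value / params$adherence$ud_chg
    },
    excess_hob_hospital = { params$costs$excess_hob_hospital <- value },
    stop("unknown sensitivity parameter `", name, "`; supported: ",
         paste(dsa_parameters, collapse = ", "), call. = FALSE)
  )
  list(params = params, wtp_override = wtp_override)
}

#' One-way deterministic sensitivity curve (UD vs TD)
#'
#' Re-evaluates the decision tree (point evaluation, no PSA) over a grid
#' of values for one parameter, holding all others at base-case values,
#' and reports the incremental HOB events averted and incremental cost of
#' universal vs targeted decolonization per 1000 admissions.
#'
#' @param param One of `p_device`, `p_mrsa`, `p_surgical`,
#'   `hrr_reduction` (treated HRR becomes `1 - value`), `wtp`,
#'   `td_relative_adherence`, `td_absolute_adherence` (converted to
#'   relative using UD CHG adherence), `excess_hob_hospital`.
#' @param values Numeric grid.
#' @param params Base `decol_params`.
#' @param perspective One element of [perspectives()].
#' @return Data frame with `param`, `value`, `hob_averted_ud_vs_td`,
#'   `inc_cost_ud_vs_td`.
#' @export
#' @examples
#' p <- build_base_case()
#' one_way_curve("p_device", seq(0.125, 0.5, by = 0.125), p,
#'               perspectives(p)$payer)
one_way_curve <- function(param, values, params, perspective) {
  rows <- lapply(values, function(v) {
    mod <- apply_dsa_value(params, param, v)
    pv <- perspective
    if (identical(param, "excess_hob_hospital") &&
        identical(perspective$name, "hospital")) {
      pv$excess_hob_cost <- v
    }
    st <- strategy_set(mod$params, c("TD", "UD"))
    ud <- evaluate_strategy(st$UD, mod$params, pv)
    td <- evaluate_strategy(st$TD, mod$params, pv)
    data.frame(param = param, value = v,
               hob_averted_ud_vs_td = td$hob_per_1000 - ud$hob_per_1000,
               inc_cost_ud_vs_td = ud$total_cost_per_1000 -
                 td$total_cost_per_1000)
  })
  do.call(rbind, rows)
}

#' Multi-way optimal-strategy grid
#'
#' Full Cartesian evaluation over up to four parameter axes; each cell is
#' a point evaluation of the three strategies followed by the dominance /
#' ICER / willingness-to-pay rule, yielding the optimal strategy for that
#' parameter combination.
#'
#' @param axes Named list of numeric grids; names as in [one_way_curve()].
#' @param params Base `decol_params`.
#' @param perspective One element of [perspectives()]; a `wtp` axis
#'   overrides its threshold cell by cell.
#' @param max_cells Refuse larger grids (guards against accidental
#'   combinatorial blow-ups); default 100000.
#' @return Data frame with one column per axis plus `optimal`.
#' @export
#' @examples
#' p <- build_base_case()
#' g <- grid_search(list(p_device = c(0.125, 0.3, 0.5),
#'                       wtp = c(0, 25000, 50000)),
#'                  p, perspectives(p)$payer)
#' table(g$optimal)
grid_search <- function(axes, params, perspective, max_cells = 1e5) {
  if (length(axes) < 1L || length(axes) > 4L || is.null(names(axes)) ||
      any(names(axes) == "")) {
    stop("`axes` must be a named list of 1-4 numeric grids", call. = FALSE)
  }
  for (nm in names(axes)) {
    if (!nm %in% dsa_parameters) {
      stop("unknown sensitivity parameter `", nm, "`; supported: ",
           paste(dsa_parameters, collapse = ", "), call. = FALSE)
    }
  }
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) > max_cells) {
    stop("grid has ", nrow(cells), " cells, above the cap of ", max_cells,
         "; coarsen the axes or raise `max_cells`", call. = FALSE)
  }
  cells$optimal <- vapply(seq_len(nrow(cells)), function(i) {
    mod_params <- params
    pv <- perspective
    for (nm in names(axes)) {
      mod <- apply_dsa_value(mod_params, nm, cells[[nm]][i])
      mod_params <- mod$params
      if (!is.null(mod$wtp_override)) pv$wtp <- mod$wtp_override
      if (identical(nm, "excess_hob_hospital") &&
          identical(perspective$name, "hospital")) {
        pv$excess_hob_cost <- cells[[nm]][i]
      }
    }
    st <- strategy_set(mod_params)
    outc <- do.call(rbind, lapply(st, function(x) {
      o <- evaluate_strategy(x, mod_params, pv)
      data.frame(strategy = o$strategy, hob_per_1000 = o$hob_per_1000,
                 total_cost_per_1000 = o$total_cost_per_1000)
    }))
    rank_and_icer(outc, pv$wtp)$optimal
  }, "")
  cells
}

#' Hospital HOB-cost threshold scatter (UD vs TD)
#'
#' Reproduces the break-even analysis from the hospital perspective: for
#' each of `n_draws` PSA iterations the net hospital cost per HOB event is
#' drawn uniformly over `hob_cost_range` (the x-variable) while all other
#' uncertain parameters are PSA-sampled, and the UD-vs-TD incremental cost
#' per 1000 admissions is recorded (the y-variable). A least-squares line
#' of y on x is fitted for each targeted-decolonization adherence level;
#' its zero crossing is the break-even hospital HOB cost above which
#' universal decolonization saves money overall.
#'
#' Because total cost is linear in the per-event cost, the fitted slope
#' estimates minus the mean incremental HOB events averted.
#'
#' @param params Base `decol_params`.
#' @param td_adherence_values Absolute TD CHG adherence levels (e.g.
#'   `c(0.71, 0.40)`).
#' @param hob_cost_range Range of net hospital cost per HOB event, US$.
#' @param n_draws PSA iterations per adherence level.
#' @param seed Integer seed.
#' @return A `decol_threshold` list with one element per adherence value:
#'   `points` (data frame `hob_cost`, `inc_cost`), `intercept`, `slope`,
#'   `break_even`.
#' @export
threshold_scatter <- function(params, td_adherence_values = c(0.71, 0.40),
                              hob_cost_range = c(0, 60000),
                              n_draws = 10000, seed = 1) {
  if (!(hob_cost_range[2] > hob_cost_range[1])) {
    stop("`hob_cost_range` is degenerate; the regression needs x spread",
         call. = FALSE)
  }
  set.seed(seed)
  out <- lapply(td_adherence_values, function(a) {
    mod <- apply_dsa_value(params, "td_absolute_adherence", a)$params
    d <- sample_parameter_draws(mod, n_draws)
    x <- stats::runif(n_draws, hob_cost_range[1], hob_cost_range[2])
    st <- strategy_set(mod, c("TD", "UD"))
    d_hob <- expected_hob_draws(st$TD, mod, d$p_hob, d$hrr_treated,
                                d$hrr_untreated) -
      expected_hob_draws(st$UD, mod, d$p_hob, d$hrr_treated, d$hrr_untreated)
    d_up <- upstream_cost_draws(st$UD, mod, d$los, d$chg_bed, d$chg_bottle,
                                d$std_bed, d$std_shower, d$mup_course) -
      upstream_cost_draws(st$TD, mod, d$los, d$chg_bed, d$chg_bottle,
                          d$std_bed, d$std_shower, d$mup_course)
    y <- d_up - d_hob * x
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    list(td_adherence = a,
         points = data.frame(hob_cost = x, inc_cost = y),
         fit = fit, intercept = unname(co[1]), slope = unname(co[2]),
         break_even = unname(-co[1] / co[2]))
  })
  names(out) <- paste0("td_", formatC(100 * td_adherence_values, format = "d"))
  structure(out, class = "decol_threshold")
}

#' @export
print.decol_threshold <- function(x, ...) {
  for (el in x) {
    cat(sprintf(
      "TD adherence %.0f%%: incremental cost = $%.0f %+.4f x (hospital HOB cost); break-even at $%s\n",
      100 * el$td_adherence, el$intercept, el$slope,
      format(round(el$break_even), big.mark = ",")))
  }
  invisible(x)
}
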