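#' Bathing strategy definitions
#'
#' Builds the three modeled strategies as per-stratum receipt probabilities
#' for chlorhexidine (CHG) bathing and the 5-day mupirocin course:
#'
#' * **SOC** (standard of care): plain-soap bathing; surgical patients
#'   receive CHG bathing at `soc_surgical_chg` (preoperative bathing
#'   convention); no mupirocin.
#' * **UD** (universal decolonization): CHG bathing for every stratum at
#'   `ud_chg`; mupirocin at `ud_mupirocin` for patients with MRSA history.
#' * **TD** (targeted decolonization): the UD regimen restricted to
#'   patients with medical devices, at `td_relative` times UD adherence
#'   (extra workflow step of identifying eligible patients); mupirocin only
#'   for device patients with MRSA history; all other strata bathed per
#'   the SOC rule.
#'
#' Adherence enters as an expected-value mixture, equivalent to
#' independent Bernoulli receipt distributed randomly across the
#' population.
#'
#' @param params A `decol_params` object.
#' @param which Character vector of strategy names to build.
#' @return Named list of `decol_strategy` objects, each with `name` and
#'   per-stratum probability vectors `chg` and `mupirocin` (length 8, in
#'   [decol_strata()] order).
#' @export
#' @examples
#' strategy_set(build_base_case())$TD$chg
strategy_set <- function(params, which = c("SOC", "TD", "UD")) {
  which <- match.arg(which, c("SOC", "TD", "UD"), several.ok = TRUE)
  s <- decol_strata()
  a <- params$adherence

  chg_soc <- ifelse(s$surgical, a$soc_surgical_chg, 0)
  defs <- list(
    SOC = list(chg = chg_soc, mupirocin = rep(0, 8)),
    UD = list(
      chg = rep(a$ud_chg, 8),
      mupirocin = ifelse(s$mrsa_history, a$ud_mupirocin, 0)
    ),
    TD = list(
      chg = ifelse(s$has_device, a$td_relative * a$ud_chg, chg_soc),
      mupirocin = ifelse(s$has_device & s$mrsa_history,
                         a$td_relative * a$ud_mupirocin, 0)
    )
  )
  out <- lapply(which, function(nm) {
    structure(c(list(name = nm), defs[[nm]]), class = "decol_strategy")
  })
  names(out) <- which
  out
}

check_strategy <- function(strategy) {
  if (!all(c("name", "chg", "mupirocin") %in% names(strategy))) {
    stop("a strategy needs `name`, `chg` and `mupirocin`", call. = FALSE)
  }
  for (nm in c("chg", "mupirocin")) {
    p <- strategy[[nm]]
    if (length(p) != 8L || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("strategy `", strategy$name, "` has `", nm,
           "` probabilities outside [0, 1]", call. = FALSE)
    }
  }
  invisible(strategy)
}

#' @export
print.decol_strategy <- function(x, ...) {
  cat("Strategy", x$name, "\n")
  print(cbind(decol_strata()["label"],
              chg = x$chg, mupirocin = x$mupirocin))
  invisible(x)
}
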