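# Independent oracles used across tests.

# Net-monetary-benefit argmax: the textbook dual of the frontier/WTP rule.
# NMB is computed against the first strategy as reference; the argmax is
# reference-invariant.
nmb_optimal <- function(outcomes, wtp) {
  nmb <- -wtp * outcomes$hob_per_1000 - outcomes$total_cost_per_1000
  outcomes$strategy[which.max(nmb)]
}

# Brute-force frontier membership: strategy i is dominated (strongly or
# extendedly) iff some convex combination of two other strategies attains
# no more cost and no more HOB, with at least one strict improvement.
brute_force_undominated <- function(outcomes, lambda = seq(0, 1, by = 0.001)) {
  n <- nrow(outcomes)
  cost <- outcomes$total_cost_per_1000
  hob <- outcomes$hob_per_1000
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (j in others) {
      for (k in others[others >= j]) {
        cmix <- lambda * cost[j] + (1 - lambda) * cost[k]
        hmix <- lambda * hob[j] + (1 - lambda) * hob[k]
        dominated <- (cmix <= cost[i] & hmix <= hob[i]) &
          (cmix < cost[i] | hmix < hob[i])
        if (any(dominated)) keep[i] <- FALSE
      }
    }
  }
  outcomes$strategy[keep]
}

# Random strategy outcomes for property tests.
random_outcomes <- function(n = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    strategy = paste0("S", seq_len(n)),
    hob_per_1000 = stats::runif(n, 1, 12),
    total_cost_per_1000 = stats::runif(n, 1e4, 3e5)
  )
}

base_params <- build_base_case()
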