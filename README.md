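# decolcea

Decision-analytic cost-effectiveness of chlorhexidine bathing and nasal
decolonization for preventing **hospital-onset bacteremia and fungemia
(HOB)** in non-ICU medical and surgical inpatients.

Hospitals choosing a bathing policy weigh three strategies: **standard of
care** (SOC: plain soap, with chlorhexidine at 50% adherence for surgical
patients), **targeted decolonization** (TD: chlorhexidine bathing for
patients with medical devices, plus mupirocin for those who also have
MRSA history, at reduced adherence), and **universal decolonization**
(UD: chlorhexidine for everyone, mupirocin for all MRSA-history
patients). `decolcea` is for hospital epidemiologists, infection
preventionists, and health-economics analysts who want this trade-off
quantified for their own case mix, willingness-to-pay, and cost
environment.

## The model

Admissions fall into 8 strata from three independent attributes (medical
device, MRSA history, surgical admission). Each stratum *g* has weight
*w<sub>g</sub>* (product of prevalences) and baseline HOB probability
*p<sub>g</sub>* (Beta(events, nonevents) from trial baseline-period
counts). Treatment effects are hazard rate ratios scoped to device
patients: HRR<sub>T</sub> = 0.86 for those who receive chlorhexidine
bathing, HRR<sub>U</sub> = 1.14 for those who do not. Expected HOB per
1000 admissions under strategy *s* with stratum chlorhexidine receipt
*c<sub>g</sub>(s)*:

```
E[HOB] = 1000 * sum_g  w_g * p_g * m_g(s)
m_g(s) = c_g(s) * HRR_T + (1 - c_g(s)) * HRR_U   (device strata; 1 otherwise)
```

Total cost = upstream (daily bathing products over a 6.5-day mean stay,
78%/22% bed-bath/shower mixture, plus $6.23 mupirocin courses) +
downstream (expected HOB events × excess cost per event: $19,643 in 2006
US$ CPI-inflated to ≈$32,538 for payers; $25,000 assumed for hospitals).
Strategies are ranked by cost; dominated strategies are removed;
incremental cost-effectiveness ratios (ICERs, $ per HOB averted) are
computed along the frontier; the optimum is the strategy with the highest
ICER at or below the willingness-to-pay threshold ($25,000 payer, $10,000
hospital). A 10,000-draw probabilistic sensitivity analysis (PSA)
propagates beta/log-normal/gamma/truncated-normal parameter uncertainty;
deterministic sensitivity analyses map where each strategy wins; an
independent patient-level microsimulation validates every cohort
expectation.

## Worked example

```r
library(decolcea)
params <- build_base_case()

run_base_case(params, "hospital")
#   strategy perspective hob_per_1000 upstream_cost_per_1000
# 1      SOC    hospital      6.60556                13202.3
# 2       TD    hospital      6.03219                14553.5
# 3       UD    hospital      5.95911                25420.7
#   downstream_cost_per_1000 total_cost_per_1000 mupirocin_treated_per_1000
# 1                   165139              178341                       0.00
# 2                   150805              165358                       7.92
# 3                   148978              174399                      70.40
```

Per 1000 admissions the hospital expects 6.6 HOB events under SOC, 6.0
under TD, 6.0 under UD; TD is cheapest ($165k total) because it buys
chlorhexidine only for the 12.5% of patients with devices, while UD
bathes everyone ($25.4k upstream) and treats 70.4 patients with mupirocin
versus TD's 7.9.

```r
rank_and_icer(run_base_case(params, "hospital"), wtp = 10000)
#  strategy hob_per_1000 total_cost_per_1000          dominance   icer
#        TD         6.03              165358        undominated     NA
#        UD         5.96              174399        undominated 123720
#       SOC         6.61              178341 strongly_dominated   NA
# Optimal at WTP $10,000 per HOB averted: TD
```

SOC is strongly dominated (more infections *and* more cost than either
decolonization strategy). UD averts 0.073 more HOB events than TD per
1000 admissions, but at $123,720 per event averted — far above a $10,000
threshold — so TD is the cost-effective choice. With uncertainty
propagated:

```r
run_psa(params, n_draws = 10000, seed = 2026)
# PSA: 10000 draws (seed 2026)
#
# payer perspective, per 1000 admissions:
#   SOC  HOB 6.6 (5.9-7.4)   total cost $228,846 ($111,027-$351,886)
#   TD   HOB 6.0 (5.5-6.7)   total cost $211,361 ($103,626-$324,601)
#   UD   HOB 6.0 (5.4-6.6)   total cost $219,823 ($111,261-$334,771)
#   UD vs TD: 0.074 HOB averted (0.028-0.122), cost +$8,462 (-2,402-31,393), ICER $114,963
#
# hospital perspective, per 1000 admissions:
#   SOC  HOB 6.6 (5.9-7.4)   total cost $178,511 ($157,530-$205,177)
#   TD   HOB 6.0 (5.5-6.7)   total cost $165,425 ($146,319-$191,571)
#   UD   HOB 6.0 (5.4-6.6)   total cost $174,449 ($148,959-$216,077)
#   UD vs TD: 0.074 HOB averted (0.028-0.122), cost +$9,023 (-1,644-31,737), ICER $122,581
```

And the hospital break-even analysis — how expensive must an HOB event be
before universal bathing pays for itself?

```r
threshold_scatter(params, td_adherence_values = c(0.71, 0.40),
                  n_draws = 10000, seed = 2026)
# TD adherence 71%: incremental cost = $10921 -0.0763 x (hospital HOB cost); break-even at $143,205
# TD adherence 40%: incremental cost = $11544 -0.3599 x (hospital HOB cost); break-even at $32,077
```

When targeting works well (71% adherence), UD only saves money if an HOB
event costs the hospital over $143k; when targeting reaches device
patients poorly (40%), the break-even drops to ≈$32k per event.

Other entry points: `one_way_curve()` and `grid_search()` (deterministic
sensitivity analyses over device prevalence, effect size,
willingness-to-pay, and TD adherence), `simulate_cohort()` /
`validate_model()` (microsimulation oracle), `load_config()` /
`write_results()` (YAML config in `inst/extdata/base_case.yaml`, CSV
output), and a command-line wrapper in `exec/decolcea` with subcommands
`basecase`, `psa`, `dsa`, `validate`. See the vignette
(`vignettes/decolonization-cea.Rmd`) for the model's assumptions, the
input readings it had to commit to, and known limitations — including a
documented ~10–15% shortfall in the UD-vs-TD incremental results relative
to the published analysis that no reading of the published inputs closes.

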