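# rxperiods

Drug use periods from prescription dispensing records.

Pharmacy dispensing registers record *purchases* — dates and amounts — but
pharmacoepidemiological questions need *exposure*: when was a person on a
drug, at what average daily dose, and when did they stop? `rxperiods`
reconstructs continuous **drug use periods** (one per person × ATC code,
with start, end and mean DDD/day) from purchase histories, for researchers
working with administrative claims or Nordic-style prescription registers.
Unlike fixed grace-period rules, the construction is driven by each
person's own purchasing pattern and by refill behavior learned from the
whole population.

## The method

For every person and ATC code, purchases are ordered chronologically and
three quantities drive a left-to-right decision walk:

1. **Sliding temporal dose average.** With DDD_i the dispensed amount at
   purchase *i* and T_i the hospital-adjusted days to the next purchase,

   DDDAVG_i = (DDD_{i-1} + 4 DDD_i + DDD_{i+1}) / (T_{i-1} + 4 T_i + T_{i+1}),

   with boundary weights (5, 1) / (1, 5) at the first/last purchase and the
   last purchase's own interval imputed from the previous dose. Net gaps
   above 300 days restart the average. The coefficient of variation of
   these averages (cv) measures purchasing regularity.

2. **Expected refill length.** ERFL_i = DDD_i (1 + 0.5 cv) / DDDAVG_i,
   clamped by package-, class- and global-level expert parameters
   (three-level hierarchy; package > finest ATC prefix > global). A
   purchase connects to the next when its ERFL covers the gap; a locally
   depressed dose average (strictly below both neighbours) is treated as
   stockpiling and may rescue the connection via the combined reach of two
   purchases.

3. **Period end.** From the last purchase the period extends by
   DDD (1 + 0.5 cv) / (DDDAVG (1 + e^-k)) days (k = purchases in the
   period), plus hospital days falling inside the extension — unless a
   continuous stay exceeds 30 days, which truncates the period at
   admission.

Around the walk, an outer loop learns per-package (vnr) refill-length
distributions from the previous iteration's periods, consolidates them to
local maxima, and feeds the modal refill length back for single purchases,
iterating until the period set is stable.

A synthetic-cohort generator (`generate_cohort()`) with regular,
stockpiling, irregular, dose-change, hospitalized, single-buyer and
restart profiles provides ground truth for validating every step without
register access.

## Worked example

The canonical stockpiling history — five purchases of 10 DDD with gaps of
10, 5, 15 and 10 days (purchase 2 buys ahead; purchase 3 uses the stock):

```r
library(rxperiods)
library(dplyr)

purchases <- read_purchases(system.file("extdata",
  "worked-example-purchases.csv", package = "rxperiods"))
pre <- preprocess_histories(sort_histories(harmonize_purchases(purchases)))
pre |> select(date, ddd_amount, raw_gap_days, ddd_avg, ddd_avg_cv)
#> # A tibble: 5 × 5
#>   date       ddd_amount raw_gap_days ddd_avg ddd_avg_cv
#>   <date>          <dbl>        <dbl>   <dbl>      <dbl>
#> 1 2005-01-01         10           10   1.09       0.195
#> 2 2005-01-11         10            5   1.33       0.195
#> 3 2005-01-16         10           15   0.8        0.195
#> 4 2005-01-31         10           10   0.923      0.195
#> 5 2005-02-10         10           NA   1          0.195
```

The dose average dips to 0.80 DDD/day at purchase 3 (expected supply
12.5 days < 15-day gap), but since 0.80 is below both neighbours the
stockpiling test fires and the walk joins all five purchases:

```r
fit <- run_pipeline(harmonize_purchases(purchases),
                    space = example_parameter_space())
tidy(fit)
#> # A tibble: 1 × 10
#>   person_id atc     start      end        total_ddd n_purchases mean_ddd_per_day
#>   <chr>     <chr>   <date>     <date>         <dbl>       <int>            <dbl>
#> 1 P1        N05AH02 2005-01-01 2005-02-20        50           5                1
```

One period: 50 DDD over 50 exposure days, 1.00 DDD/day, ending ten days
(the last purchase's supply) after the last purchase. `glance(fit)`
summarises the fit; `autoplot(fit)` draws period timelines;
`purchase_audit(fit)` reports the decision branch taken at every purchase.

A thin command-line front end ships in `inst/cli/rxperiods.R`
(`run`, `simulate`, `validate-config`, `score`).

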