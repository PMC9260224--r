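# campaignimpact

Does engaging with an online health-awareness campaign change how people
talk afterwards? `campaignimpact` answers that question for streams of
timestamped social-media posts, the setting of awareness weeks run by health
nonprofits: it detects campaign engagement, aligns each engaged user's
timeline on their **day 0** (the first campaign-matching post), scores
each user-day's language against a category lexicon, and estimates, per
category, how the engaged cohort's language diverged from the counterfactual
implied by a control cohort of users who discussed diet/health topics but
never touched the campaign.

It is written for computational social scientists and public-health analysts
who work in R with tabular data: every stage takes a data frame and returns
a tibble, so the pipeline composes with dplyr, and fitted objects have
`tidy()` / `glance()` / `autoplot()` methods.

## The model at the core

For each lexicon category, let $y_t$ be the target cohort's mean daily rate
(matching tokens / tokens, averaged over users) on relative day $t$, and
$x_t$ the control cohort's. A local-level structural time-series model with
one control covariate,

$$y_t = \mu_t + \beta x_t + \varepsilon_t,\quad
  \mu_{t+1} = \mu_t + \eta_t,\quad
  \varepsilon_t \sim N(0,\sigma^2_{\mathrm{obs}}),\
  \eta_t \sim N(0,\sigma^2_{\mathrm{lvl}}),$$

is fitted to the 15 pre-engagement days by Kalman-filter maximum likelihood,
with $(\mu_t, \beta)$ carried in the state under diffuse initialization so
their joint estimation uncertainty survives into the prediction. Simulated
post-period trajectories give the counterfactual "had the engagement never
happened"; the **relative effect** is

$$\frac{\sum_t y^{\mathrm{post}}_t - \sum_t \hat y^{\mathrm{cf}}_t}
       {\sum_t \hat y^{\mathrm{cf}}_t},$$

reported with a predictive interval and a two-sided tail-area p-value, and
flagged across categories at the 0.05 and Bonferroni (`alpha / n_categories`)
tiers. Around the estimator sit cohort construction with a ≥3-posts-per-window
activity filter, display-name gender inference (honorifics, first-name lists,
an ambiguity rule), campaign-reach statistics (follower sums, Welch t and
Mann-Whitney U comparisons, Walktrap retweet-network communities), gendered
odds-ratio word rankings (Haldane–Anscombe smoothed), and a synthetic corpus
generator with known ground truth that backs the whole test suite.

## A worked example

Simulate a campaign corpus with a known +50% lift on the *Risk* category,
then run the full study:

```r
library(campaignimpact)
library(dplyr)

cfg <- corpus_config(n_target_users = 120, n_baseline_users = 240,
                     category_base_rates = c(Female = 0.05, Risk = 0.02,
                                             Posemo = 0.05),
                     injected_lifts = c(Risk = 0.5), seed = 33)
sim <- simulate_corpus(cfg)

res <- run_study(sim$posts,
                 study_config(seed = 33, impact = impact_config(n_sim = 400),
                              lexicon = read_liwc_dic(keep = c("Female",
                                                               "Risk",
                                                               "Posemo")),
                              groups = "all"))
select(res$impact, category, relative_effect, ci_lower, ci_upper,
       p_value, significance)
#> # A tibble: 3 × 6
#>   category relative_effect ci_lower ci_upper p_value significance
#>   <chr>              <dbl>    <dbl>    <dbl>   <dbl> <chr>
#> 1 Risk              0.517    0.326    0.794  0.00499 bonferroni
#> 2 Female            0.0276  -0.0456   0.117  0.519   none
#> 3 Posemo           -0.0549  -0.114    0.0198 0.150   none
```

The planted lift is recovered — *Risk* shows a +51.7% relative effect with
interval [+32.6%, +79.4%], significant past the Bonferroni tier — while the
two unlifted categories sit near zero with unremarkable p-values. The report
also carries cohort sizes, gender shares computed over eligible users,

```r
res$gender_shares
#> # A tibble: 3 × 4
#>   label       n share   pct
#>   <chr>   <dbl> <dbl> <dbl>
#> 1 female    136 0.378  37.8
#> 2 male       64 0.178  17.8
#> 3 unknown   160 0.444  44.4
```

reach statistics, retweet-network communities, and the gendered odds-ratio
word table for the significant categories. `autoplot(res$impact$result[[1]])`
draws the standard three-panel intervention plot (observed vs counterfactual,
pointwise effect, cumulative effect).

Real corpora enter through `read_corpus()` (JSON Lines, one post per line)
and are checked by `validate_corpus()`; lexicons load from the LIWC `.dic`
dialect via `read_liwc_dic()`. The bundled dictionary is a small synthetic
stand-in covering nine categories — substitute a full dictionary in the same
format for real analyses.

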