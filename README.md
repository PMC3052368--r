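# dgrecruit

When are neurons born in the adult brain recruited into the network that
processes spatial information? In the rat dentate gyrus (DG), new granule
neurons develop a specific Arc-expression response to spatial exploration
only once they are about 30 days old (in ~5% of the cohort), and that
responsiveness declines as they age further. `dgrecruit` implements the
quantitative model built on those pulse-chase (BrdU/Arc) observations,
for neuroscientists and modellers who want to reproduce, probe or extend
it:

- a **linear responsiveness probability** `P(a) = α + r·a` of neuron age,
  fitted by OLS, with its extrapolated zero crossing (the age past which
  adult-born neurons are predicted to no longer respond);
- a **power-law cohort survival curve** `N(τ) = N₀·τˢ` for the number of
  neurons born on day `τ` that survive their first month, anchored to an
  observed cohort (`N(150) = 345`);
- their **convolution** `R(t) = Σ N(τ)·P(t−τ)` over the animal's life
  span — the predicted number of adult-born neurons recruited by
  exploration at each age — with its peak and its share of the total
  responding population;
- the **early non-specific Arc background** in 1–30-day-old neurons
  (two-segment linear model, convolved with the as-found young-cohort
  sizes);
- the **census arithmetic** linking sampled counts to region- and
  DG-level populations; and
- a **synthetic-data generator** for study-shaped per-animal count
  tables, with seeded parameter-recovery experiments.

## Worked example

```r
library(dgrecruit)
res <- run_pipeline(pipeline_config())
cat(res$report, sep = "\n")
```

```
variant: adult (cohorts from day 70)
responsiveness: P(age) = 0.055947 -0.000185965 * age; R^2 = 0.9989
zero crossing: 300.85 d (reported 301)
survival: N(tau) = 2218.2 * tau^-0.3714, anchored N(150) = 345
recruitment peak: 2084 cells at animal age 318 d (recruitment day 219)
share of responding population: 60.2% of 3465 cells
early background: max 0.172% of 231000 granule cells
background vs cage-control Arc (0.31%): 55.5%
background vs exploration Arc (1.50%): 11.5%
census: 231000 region cells; 3465 responding; 1800 daily surviving births
```

Reading the report: the fitted line loses all responsiveness at ~301
days of neuron age; convolving cohort survival with that line predicts a
peak of ~2084 adult-born cells responding to exploration — about 60% of
the 3,465 granule cells that respond in the same region, i.e. at the
peak the majority of the spatial-exploration response is carried by
adult-born neurons. The peak is reported both as an animal age (318 d)
and on the recruitment-day axis (day 219, counting from the first day an
adult-born cohort can respond); see the vignette for why the published
headline day lives on the second axis. The background block says that
unstimulated Arc expression in very young neurons can account for at
most ~0.17% of granule cells — roughly half the cage-control Arc level
but only ~11% of the exploration response.

Individual stages are plain functions (`fit_responsiveness()`,
`power_survival_model()`, `recruitment_curve()`, `peak_recruitment()`,
`early_background_curve()`, `generate_study()`, ...) and compose to the
same results as `run_pipeline()`. A thin command-line wrapper lives at
`inst/cli/dgrecruit.R`.

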