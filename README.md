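# seqtrace

Do animals remember stimulus *sequences* faithfully — order and identity —
or only as an unstructured collection of decaying memory traces? `seqtrace`
is an R package for researchers in comparative cognition who want to work
with that question quantitatively. It implements the memory-trace model of
sequence representation, simulates the three behavioural paradigms used to
test it in bonobos and humans, reproduces the count-based statistics such
studies report, and makes the trace-model fit (and its identifiability
limits) executable.

## The model

A stimulus shown for $d$ seconds lays down a trace of intensity
$1 - e^{-g d}$ (encoding rate $g$), which then decays as
$e^{-\lambda t}$; intensities add over repeated presentations. Choice among
displayed options depends only on these intensities, through a softmax with
inverse temperature $\beta$ and lapse rate $\varepsilon$, or through
Gaussian-noise-perturbed maximisation (s.d. $\sigma$). Delayed
matching-to-sample accuracy is summarised by the retention curve
$p(t) = c + (1-c)\,a\,e^{-\lambda_r t}$ with chance level $c$. For a
two-stimulus probe sequence, the probability of choosing the first sample
is increasing in its duration and decreasing in the second stimulus'
duration — the signature the probe design tests.

Five function families cover the workflow: the trace model
(`trace_params()`, `trace_state()`, `probe_prediction()`,
`retention_curve()`), schedulers and agents (`schedule_*()`,
`trace_agent()`, `faithful_agent()`, `run_task()`), statistics
(`binom_test_two_sided()`, `chisq_contingency()`, `windowed_criterion()`,
`block_performance()`, `probe_tables()`, `delay_performance()`),
maximum-likelihood fitting (`fit_retention()`, `fit_trace_probes()`,
`lr_test()`, `recovery_study()`), and the synthetic-study generator
(`generate_study()`, `write_study()`, plus the published probe-count
tables via `reference_probe_counts()`).

## Worked example

The two bonobo subjects' published probe-choice tables ship with the
package. Teco's 6 × 2 table (choices of the first vs second sample stimulus
under six duration conditions):

```r
library(seqtrace)
tabs <- reference_probe_counts()
chisq_contingency(tabs$teco)
#> Pearson chi-squared test
#>   statistic = 5.0625, df = 5
#>   n = 94, p = 0.4083
```

The homogeneity test says choice did not differ across probe types
(p = 0.41). Yet responding was far from random with respect to *matching*:
Kanzi picked one of the two sample stimuli on 116 of 120 probes,

```r
pt <- probe_tables(reference_probe_log("kanzi"))
binom_test_two_sided(pt$matching_count, pt$probe_total)
#> Exact binomial test (two-sided, p0 = 0.5)
#>   statistic = 0.9667
#>   n = 120, p = 1.279e-29
```

so the samples were remembered, but not in a way that the probe durations
modulated. Fitting the retention curve to synthetic delayed
matching-to-sample counts generated at the study-like parameters
($a = 0.7$, $\lambda_r = 0.25$, 500 trials per delay):

```r
set.seed(42)
rp <- retention_params(asymptote = 0.7, decay_rate = 0.25)
delays <- c(0, 2, 5, 10)
k <- rbinom(4, 500, retention_curve(delays, rp))
fit <- fit_retention(delays, k, rep(500, 4))
summary(fit)
#> Retention-curve fit (n = 2000)
#> Estimates:
#>  asymptote decay_rate
#>     0.7212     0.2278
#> log-likelihood: -13.039  converged: TRUE
#> Standard errors:
#>  asymptote decay_rate
#>     0.0296     0.0277
#> deviance vs chance-level null: 429.0121
```

Both parameters are recovered within one standard error. Fitting the trace
model to Teco's probe table, by contrast, shows why the original fit was
abandoned: the profile interval for the decay rate runs to the parameter
bound —

```r
ft <- fit_trace_probes(tabs$teco)
summary(ft)
#> Trace-model probe fit (n = 94)
#> Estimates:
#>       decay temperature
#>      1.4690      1.8127
#> log-likelihood: -9.218  converged: TRUE
#> Profile confidence intervals:
#>              lower  upper
#> decay       0.4486 10.000
#> temperature 0.9868  3.067
#> deviance vs chance-level null: 25.3074
```

— the data constrain a general recency preference (hence the deviance
against the chance null) but not the duration signature itself: the
likelihood-ratio homogeneity check across probe types,

```r
lr_test(fit_probe_null(tabs$teco, "saturated"),
        fit_probe_null(tabs$teco, "equal_choice"), df = 5)
#> Likelihood-ratio test
#>   statistic = 4.6824, df = 5
#>   n = 94, p = 0.4559
```

finds no per-condition structure, in agreement with the Pearson test above.

A complete synthetic study (four trace-driven "bonobos", five faithful
"humans", with ground truth) is one call:

```r
study <- generate_study(study_config(seed = 1))
write_study(study, "study_out/")
```

A thin command-line wrapper over the same functions lives at
`inst/cli/seqtrace.R` (subcommands `simulate`, `analyze`, `fit`, `synth`).

## Package layout

- `R/` — trace model, schedulers, agents, statistics, fitting, synthetic
  data
- `tests/testthat/` — unit, property and end-to-end tests
- `vignettes/trace-memory-methods.Rmd` — the model, its assumptions, design
  decisions and limitations
- `inst/cli/seqtrace.R` — command-line wrapper
- `scripts/acceptance.R` — headline-quantity reproduction
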