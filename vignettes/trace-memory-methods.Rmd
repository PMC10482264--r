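---
title: "Memory traces, sequence discrimination, and how seqtrace models them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory traces, sequence discrimination, and how seqtrace models them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtrace)
```

## The scientific question

Do animals remember a sequence of stimuli *faithfully* — preserving the order
and identity of what they saw — or only as an unstructured collection of
decaying memory traces? Under the trace hypothesis, after seeing the sequence
"blue, then yellow", an animal retains two scalar intensities, one per
stimulus, with the more recent (or longer) stimulus carried by the stronger
trace; nothing encodes which came first. Faithful sequence memory, by
contrast, keys behaviour on the ordered pair itself. The two representations
make sharply different predictions for a two-choice discrimination in which
the sequence AB must be answered on the left and AA, BA and BB on the right:
a trace learner without decay literally cannot distinguish AB from BA, while
a faithful learner solves all four mappings quickly.

`seqtrace` implements the trace model, simulates the three behavioural
paradigms used to test it in bonobos and humans, reproduces the count-based
statistics of such studies, and makes the planned-but-abandoned model fit
executable, including the parameter-recovery evidence for when that fit is
trustworthy.

## The trace model

A presentation of duration $d$ seconds lays down an initial intensity

$$ I_0(d) = 1 - e^{-g d}, $$

with encoding rate $g > 0$ per second (default 1). The saturating form keeps
intensities bounded by 1, so the 4.5-second probe durations used in the probe
design cannot dominate pathologically; a linear law $g d$ is available via
`trace_params(encoding = "linear")` for sensitivity analyses. After its
offset the trace decays exponentially at rate $\lambda \ge 0$ per second, and
intensities add over repeated presentations of the same stimulus:

$$ I_s(t) = \sum_{\text{events of } s} \left(1 - e^{-g d}\right)
            e^{-\lambda (t - \text{offset})}. $$

Choice among displayed options is driven only by these intensities, evaluated
at the onset of the response options (the rendering latency is taken as 0 s).
Two response rules are provided:

* **softmax** (`choice_probabilities(..., rule = "softmax")`): probabilities
  proportional to $e^{\beta I}$ with inverse temperature $\beta \ge 0$,
  mixed with a lapse rate $\varepsilon$ towards the uniform distribution
  over the displayed options. This smooth rule is what the fitting routines
  use.
* **noisy max** (`rule = "noisy_max"`): each intensity is perturbed by
  independent zero-mean Gaussian noise of s.d. $\sigma$ and the maximum is
  chosen. The win probabilities are computed exactly by one-dimensional
  Gauss–Hermite quadrature, so the function stays deterministic; sampling
  randomness lives entirely in the agents. A Weber-style multiplicative
  noise was considered and rejected as a default because the probe
  conditions span durations (0.5–4.5 s) whose saturating intensities differ
  by less than a factor of 3, leaving the two noise models practically
  indistinguishable at the study's sample sizes; the additive model keeps
  the chance-level algebra transparent. The same lapse mixture is applied
  after both rules, for consistency.

For a two-stimulus probe sequence (durations $d_1$, $d_2$, inter-stimulus
interval 0.3 s, retention gap 0 s before the options), `probe_prediction()`
returns the probability of choosing the *first* sample conditional on a
sample being chosen. Because the elapsed time from the first stimulus' offset
to the decision is $\mathrm{isi} + d_2$ regardless of $d_1$, this probability
is strictly increasing in $d_1$ and strictly decreasing in $d_2$ — the
signature the probe design was built to detect. With $\lambda > 0$ and equal
durations it is below one half: recency.

Retention in delayed matching-to-sample is summarised by the exponential
retention curve

$$ p(\text{correct} \mid \text{delay } t) = c + (1 - c)\,a\,e^{-\lambda_r t}, $$

with chance level $c$ (0.5 for two options), amplitude $a \in [0, 1]$ and
forgetting rate $\lambda_r \ge 0$. The source material reports only the
qualitative pattern (above chance to five seconds, near chance at ten), so
the exponential form is our design choice — it is the standard single-rate
forgetting description, it nests "no memory" ($a = 0$) and "no forgetting"
($\lambda_r = 0$), and its predictions never leave $[c, 1]$.

## The paradigms and their schedulers

The schedulers reproduce the designs exactly, and every composition rule is
asserted by tests:

* `schedule_mts()` — simultaneous and zero-delay matching-to-sample with the
  blue/yellow sample colour and the correct side each balanced 5/5 within
  every aligned 10-trial window.
* `schedule_delayed_mts()` — delays $\{0, 2, 5, 10\}$ s with every second
  trial a 0-s delay (keeping reward rates high); the non-zero delays are
  drawn as shuffled balanced blocks, our reading of "pseudo-random order"
  (the source does not define it, and per-delay exposure differed between
  its subjects; we expose the counts instead of replicating idiosyncrasy).
* `schedule_sequence_task()` — 18-trial blocks of 9 AB / 3 AA / 3 BA / 3 BB
  in random order; AB rewards left, everything else right; 1 s stimuli,
  300 ms gap. Colour-role assignment (which colour plays A) is
  counterbalanced metadata; agents never see role labels.
* `schedule_probe_phase()` — four-alternative matching baseline (1 s sample,
  pool of 20 pictorial stimuli, three random foils) with exactly one
  unrewarded probe per 10-trial block at a uniformly random position; probes
  draw two distinct stimuli and one of six duration conditions
  ($d_1/d_2 \in \{0.5/1, 1.5/1, 4.5/1, 1/0.5, 1/1.5, 1/4.5\}$, 20
  repetitions each by default). The probe-sequence inter-stimulus interval
  is not stated in the source; we reuse the sequence task's 0.3 s. The gap
  between the second stimulus and the options is taken as 0 s.

`run_task()` executes a schedule with an agent, implementing the correction
procedure (an incorrect sequence-task response re-inserts the same trial,
flagged, until answered correctly), recording probe responses without reward
or learning, and writing a `trial_log` whose CSV schema is documented in
`?write_trial_log`. All randomness flows from the seed passed to the
scheduler/runner; the caller's RNG state is saved and restored.

The blackout punishments (3 s sequence task, 5 s probe task) affect only
session time, which the package does not model; they carry no learning
signal here. The 120-trial daily cap is available via `assign_sessions()`
and off by default.

## Agents

* `random_agent()` — the chance baseline.
* `trace_agent()` — perceives only noisy trace intensities. On matching
  trials it picks the option with the highest perceived intensity (lapse
  aside). On sequence trials it sees $x = (m_1, m_2, 1)$, the two colour
  intensities at decision time plus a bias term, holds linear action values
  $w_s \cdot x$ per side, chooses by softmax and updates the chosen side by
  the delta rule $w \leftarrow w + \alpha (r - v) x$. With $\lambda = 0$,
  AB and BA generate identical feature distributions, so no amount of
  training can separate them — the core prediction.
* `faithful_agent()` — tabular action values keyed by the ordered sequence
  identity, delta-rule updates, $\varepsilon$-greedy policy. Initial values
  are optimistic (0.5) so that an unrewarded error is informative: with
  learning rate 1 each sequence key costs at most one greedy error, which
  is what produces the near-immediate acquisition seen in human subjects.

Because AB and BA reward opposite sides, any response policy that cannot
tell them apart has expected *balanced* accuracy
$(\hat P(\text{correct}\mid AB) + \hat P(\text{correct}\mid BA))/2 = 0.5$,
however side-biased it is (AB is three times as frequent as BA, so raw
pooled accuracy is not chance-proof). `discrimination_accuracy()` therefore
reports balanced accuracy with a two-sided normal chance band using the
pooled side-choice proportion as the null response probability.

## Statistics

`binom_test_two_sided()` implements the exact two-sided binomial test by the
minimum-likelihood convention (sum the probabilities of all outcomes no more
likely than the observed one), matching standard statistical software; tests
verify it against an exhaustive enumeration oracle for all $n \le 12$ and
against the reference implementation at larger $n$. `chisq_contingency()` is
the Pearson test with margin-based expectations, no continuity correction by
default. `windowed_criterion()` scans for 80% correct over the last 20
trials within a session (sessions are never straddled);
`block_performance()` reports per-120-trial-block proportions, correction
trials included, final partial blocks flagged; `probe_tables()` cross-
tabulates probe choices into the 6 × 2 chose-first/chose-second table plus
the matching count; `delay_performance()` gives the per-delay summary with
Wilson 95% intervals (the source says only "95% confidence intervals";
Wilson has better small-sample coverage than Wald and is our default).
Reported percentages are rounded only at the reporting layer; everything
internal is full precision.

On the published probe counts, the package reproduces the homogeneity
chi-squared of the second subject exactly (5.06 on 5 df, p = 0.41). For the
first subject our computation gives 8.48 (p = 0.13); the printed statistic
for that subject ("6, 48") is inconsistent with its own printed p-value,
which matches 8.48 on 5 df, so we report the computed value and assert
nothing about the printed one.

## Model fitting

`fit_retention()` fits $(a, \lambda_r)$ by maximum likelihood under
independent binomial counts, with bounded L-BFGS-B from 8 fixed multi-starts
(objective tolerance 1e-8). Chance-level data are not an error: the fit
returns $a = 0$ with a `flat_likelihood` diagnostic and
`decay_rate_unidentified`, the graceful version of the degenerate case.

`fit_trace_probes()` fits the trace model to the 6 × 2 probe table via
$k_i \sim \mathrm{Bin}(n_i, \pi_i)$ with $\pi_i$ the probe prediction. With
six conditions and ~20 choices each, $(g, \lambda, \beta)$ are jointly
weakly identified (the likelihood has a ridge trading gain against
temperature), so the default pins $g = 1$ and $\varepsilon = 0$ and
estimates $(\lambda, \beta)$; the pins are user-changeable. Confidence
intervals are profile-likelihood (re-optimising the other parameter at each
fixed value), not Wald, because the counts are small; interval endpoints
that hit the parameter box are reported at the box. Three reference models
support likelihood-ratio assessment via `fit_probe_null()`: chance
($\pi = 0.5$), equal-choice (one common $\pi$, whose comparison against the
saturated model with df = rows − 1 is the likelihood-ratio analogue of the
Pearson homogeneity test), and saturated. The distinction matters: a
constant preference for the second sample (recency) moves every row off
0.5 without any duration signal, so "different from chance" and "modulated
by duration" are different questions, and the package keeps them separate.

`recovery_study()` closes the loop: simulate at known parameters, refit,
report bias, RMSE and CI coverage. At the study's own probe design scaled to
2,000 choices per condition, the decay rate is recovered inside its profile
95% interval in well over 90% of replicates; at the study's actual 20
repetitions per condition the likelihood is nearly flat — which is the
quantitative way of saying the original design could not have constrained
the model, and why the degenerate-fit path is a first-class citizen.

## The synthetic study

`generate_study()` produces the full study shape: four bonobo-like trace
subjects (delayed matching-to-sample, 2,304 sequence-task trials scheduled —
every subject exceeds the 2,300 minimum — and a 120-probe phase) and five
human-like faithful subjects (sequence task only), with per-subject
parameters jittered log-normally (relative s.d. 0.1) around the config means
to emulate between-subject spread. Ground truth (every parameter and seed)
is written alongside the logs; regeneration from the same config is
byte-identical.

The defaults are calibrated to the study's observed regimes, chosen once at
design time:

* retention means $a = 0.7$, $\lambda_r = 0.25$ reproduce the reported
  per-delay accuracies (≈85% at 0 s, ≈71% at 2 s, ≈58% at 5 s, ≈55% at
  10 s);
* trace-agent perception/learning ($\sigma = 1.2$, $\alpha = 0.02$,
  $\beta = 3$, $\lambda = 0.5$) places simulated bonobos in the
  near-chance final-block regime with Table-1-like spread (final-block
  per-type accuracies scattered roughly 30–75%);
* faithful-agent settings ($\alpha = 1$, $\varepsilon = 0.1$) give
  criterion passage within a few dozen trials, like the human subjects.

DMTS responses are drawn directly from the subject's retention curve rather
than through the trace agent: the retention curve *is* the behavioural
summary being emulated, and routing it through an agent would only add a
second parameterisation of the same curve.

What the generator deliberately does **not** emulate: session refusals,
motivation drifts, unequal per-delay exposure between subjects, the real
(undocumented) schema of the deposited dataset, or any pictorial content of
the stimuli. Passing tests on synthetic data therefore demonstrate that the
pipeline's logic and statistics are correct under the model's assumptions —
not that real bonobo behaviour satisfies those assumptions.

## Numerical choices and degenerate inputs

* Binomial likelihoods clamp probabilities to $[10^{-12}, 1 - 10^{-12}]$
  before taking logs.
* Softmax subtracts the maximum before exponentiating.
* Gauss–Hermite quadrature uses 61 nodes via the Golub–Welsch
  eigen-decomposition; $\sigma = 0$ degenerates to argmax with ties split
  uniformly.
* `lr_test()` tolerates deviance down to $-10^{-8}$ (optimizer noise) and
  errors below that, naming the optimization failure.
* Schedulers reject empty delay sets, pools smaller than the four displayed
  options, and non-positive sizes; a trial count that breaks the 10-trial
  balance window is honoured with a warning, the final partial window drawn
  without the balance guarantee.
* Ties in the faithful agent's greedy step are split uniformly at random.

## Problem sizes used in the checks

The package's own validation runs at sizes chosen to make the checks sharp
but desk-sized: retention recovery at $10^5$ trials per delay (absolute
errors well under 0.02), trace-model recovery at 2,000 choices per condition
over 50 replicates, the agent contrast over 100 seeded runs of 100+ trials
(faithful) and 2,304-trial schedules (trace), and probe-position uniformity
over 10,000 scheduled blocks. These sizes are the package's choices for
statistical resolution; all are reproduced by `scripts/acceptance.R` and the
test suite from a single seed.

## Known limitations

* The trace model's functional forms (saturating encoding, single
  exponential decay, additive Gaussian decision noise) are declared design
  choices; the source material never states the model as equations.
* The retention fit treats trials as independent Bernoulli draws, ignoring
  within-session learning or motivation trends.
* The probe fit conditions on sample-stimulus choices and assigns
  non-matching options intensity zero; stimulus-specific familiarity or
  bias is not modelled.
* Humans and bonobos differ in far more than the representation contrast
  the two agents isolate; the agents are hypotheses made executable, not
  subject models.
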