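---
title: "Quantifying olfactory sensory neuron input: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying olfactory sensory neuron input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osnresponse)
```

Olfactory sensory neurons (OSNs) are born throughout life, and immature
OSNs already project axons into olfactory-bulb glomeruli. Asking whether
that immature input is functional requires the same quantitative toolkit at
three levels: odorant-evoked calcium signals in glomeruli (amplitude,
tuning, concentration coding), synaptic currents evoked by optogenetic
activation of OSN axons (kinetics and monosynaptic classification), and
behavioral read-outs of odor detection and discrimination. `osnresponse`
implements that toolkit as a tested pipeline, together with seeded
synthetic-data generators that emulate the experimental designs and retain
ground truth, so every statistic can be validated by parameter recovery.

This vignette records the models, the conventions adopted where a published
verbal definition leaves freedom, and the reasoning behind each choice.

## Glomerular response metrics

A trial is 20 s of fluorescence sampled at 10.17 or 15 frames/s: 4 s
baseline, 1 s odorant, 15 s post-stimulus; three trials per stimulus are
averaged pointwise before any metric is computed. Time is seconds from
trial start, with sample 0 at *t* = 0, which keeps the two acquisition
rates interchangeable.

On the averaged trace, with stimulus onset at $t_0$:

* **baseline**: mean $F_0$ and SD $\sigma_0$ over the 1 s window ending at
  $t_0$;
* **peak**: maximum sample in $(t_0, t_0 + 3\,\mathrm{s}]$, earliest frame
  on ties;
* **responder rule**: $\Delta F = F_\mathrm{peak} - F_0 > 3\sigma_0$;
* **amplitude**: $\Delta F/F = 100\,\Delta F / F_0$ (%), reported for
  responders and set to an explicit 0 for non-responders, because the
  concentration analysis averages over glomeruli that did not respond at
  every concentration;
* **latency**: time from $t_0$ to the first whole frame exceeding
  $F_0 + 3\sigma_0$ — the responder threshold reused as the detection
  level, with no sub-frame interpolation, so latency is quantised at one
  frame;
* **time to peak**: peak time minus $t_0$; always $\ge$ latency;
* **response integral**: $\sum 100\,(F - F_0)/F_0 \cdot \Delta t$ from
  $t_0$ to the end of the trial (% · s). The trial end is the only
  boundary every trial shares, so it is the integration limit.

Amplitudes are reported as increases: $\Delta F/F$ is positive for a
fluorescence rise. If the baseline SD is exactly zero (noise-free synthetic
input) the responder rule degrades to $\Delta F > 0$, which keeps
closed-loop tests well defined. A baseline mean $\le 0$ makes every ratio
metric meaningless and raises an error rather than propagating nonsense.

Blank subtraction removes the mechanosensory component: the $\Delta F/F$ of
the deodorized-air blank is subtracted from every odorant amplitude of the
same glomerulus. Responder status is then re-evaluated as *(responder) and
(blank-subtracted amplitude > 0)* — whether the original analysis
re-screened after subtraction is not documented, so the package makes the
conservative choice explicit and applies it everywhere. The baseline SD is
taken from the trial-averaged trace (not per-trial), because all metrics
are defined on that trace.

```{r step-demo}
sched <- stim_schedule("odorA", "odorA", 0.01, FALSE, onset_s = 4,
                       duration_s = 1, trial_length_s = 20,
                       sampling_rate_hz = 15)
trace <- rep(100, 300)
trace[61:75] <- 150  # step to 150 during the stimulus
compute_response(trace, sched[1, ])[, c("dff_pct", "is_responder")]
```

## Odorant tuning

Lifetime sparseness over an $n$-odorant panel,

$$S_L = \frac{1 - \left(\sum_i r_i / n\right)^2 / \left(\sum_i r_i^2 / n\right)}{1 - 1/n},$$

with the numerator's first term the *squared mean* of the response vector.
This is the standard lifetime-sparseness form and the only reading that
satisfies the defining limits ($S_L = 0$ for uniform responding, $S_L = 1$
for a single-odorant response); the tests assert both limits and
scale invariance. Inputs $r_i$ are blank-subtracted amplitudes floored at
zero, with non-significant odorants contributing 0 — negative inputs would
break the $[0, 1]$ range. $S_L$ is computed only for glomeruli responding
to at least one odorant; an all-zero vector has no defined selectivity and
errors rather than returning a value.

## Concentration coding

The ladder is 0.5, 1, 5, 10% v/v (stored as fractions, displayed as
percent). Three summaries:

* **per-mouse means including zeros** — a glomerulus enters the analysis
  for an odorant if it responds to at least one concentration; at
  concentrations where it did not respond it contributes an explicit 0, so
  per-mouse means are over a fixed glomerulus set rather than a
  concentration-dependent one;
* **normalization to the top concentration** — each glomerulus's
  amplitudes are divided by its 10% response before per-mouse averaging,
  giving every responsive glomerulus equal weight; glomeruli without a
  positive 10% response are excluded from this analysis (and counted in a
  log message), since their normalizer is undefined;
* **ascending pair differences** — for each adjacent ladder pair
  (0.5–1%, 1–5%, 5–10%) and each glomerulus responding at *both*
  concentrations, metric(high) − metric(low), then per-mouse means of the
  available differences. Only adjacent pairs are computed. The sign
  convention (higher minus lower) makes a latency shortening negative.

The package exposes both the include-zeros means and the respond-at-both
pair differences rather than collapsing them, because they answer slightly
different questions (population drive vs within-glomerulus change).

## Saturation diagnostic

Indicator saturation truncates the rising phase: fluorescence climbs
steeply and then stops rising within a frame or two, rather than rolling
over smoothly. On the frame-difference series $d_t = F_t - F_{t-1}$ of the
averaged trace, the diagnostic finds the maximal rise (earliest frame on
ties) and counts frames from the *next* frame to the first $d_t \le 0$;
counts of 1–2 flag the response. Only responses with $\Delta F/F$ above the
screening threshold (default 1000%) are evaluated — smaller responses are
nowhere near the indicator's ceiling and the signature is uninformative
there. A trace that rises monotonically to the end of the trial yields a
warning and no flag. Counting starts after the max-rise frame because the
maximal rise itself is by definition positive; the tests exercise the
alternative (inclusive) convention only to document that the choice
matters by exactly one frame.

## EPSC kinetics

Sweeps are baseline-subtracted over the 350 ms before light onset and
averaged. The peak is the most negative value of the averaged trace within
250 ms after onset; the cell responds if the peak magnitude exceeds 3 SDs
of the averaged trace's baseline; a responding cell is monosynaptic if its
onset latency is under 2 ms.

Onset is defined at 5% of peak. Two implementation details matter:

* **the crossing is located on the rising edge into the peak** (walking
  back from the peak to the first sample at or below the level), not as
  the first post-stimulus sample below the level — in a noisy trace the
  latter can fire on a baseline noise dip long before the response. The
  walk is clamped at light onset, since a response cannot precede its
  stimulus. No interpolation: the onset is a whole sample.
* **the reported onset is the mean of the per-sweep onset latencies**, the
  same latencies whose sample SD (n−1) is the jitter. Locating the onset
  on the jitter-smeared *average* instead would bias it early by roughly
  one jitter SD: the foot of a synaptic current is a hinge, so the average
  of time-shifted sweeps crosses a low threshold as soon as its earliest
  trials have risen. The per-sweep mean is unbiased for the true onset,
  and parameter-recovery tests confirm it to within two sample intervals
  at adequate signal-to-noise. Per-sweep crossings use the averaged-trace
  5% level so all trials are measured against one reference; sweeps that
  never reach the level carry no onset and are excluded from the jitter.

Time to peak is the averaged-trace peak time minus the onset. Power curves
(3 light durations × 5 intensities) report one metrics row per recorded
condition; missing conditions are reported absent, never zero-filled.
Exclusion on membrane-potential grounds (> −45 mV) is an input-level flag,
not a computation — current-clamp data are out of scope.

Recovery bounds are meaningful only where the 5% level clears the noise
floor. At the generator's own low end (|peak| 10 pA on 10 pA RMS noise,
10 sweeps) the level is fractions of the averaged noise SD and no estimator
can locate it; the test suite therefore evaluates the onset and jitter
bounds as medians over cells with SNR ≥ 5, the same gate used for the
classification accuracy check.

## Behavioral scoring

* **Two-choice detection**: investigation ratio = odor / (odor + mineral
  oil) sniffing time; 0.5 is chance, and a ratio of 0.75 — odor sniffing
  three times the control — is the detection threshold. The comparison is
  inclusive (≥ 0.75), reading "a ratio of 0.75 indicates detection"
  literally. Zero total sniffing leaves the ratio undefined and scores as
  not detected.
* **Habituation–dishabituation**: four odorants (water, almond, mint,
  vanilla) in fixed order, three trials each. Habituation(odorant) =
  trial 1 − trial 2; dishabituation(transition) = first trial of the next
  odorant − last trial of the previous. Water occupies an ordinary
  position in the sequence, so the first transition is water→almond.
  Per-subject summaries are arithmetic means over the four odorants and
  the three transitions — the combiner is not documented in the source
  protocols, and the unweighted mean is the only choice that treats
  odorants symmetrically.
* **Buried food**: pass if the food is found within 600 s; failures carry
  the censored 600 s latency *and* a pass flag, so downstream comparisons
  can either use censored latencies or exclude failures — which of the two
  the original analysis did is not recorded. Acclimation digging time is
  carried through as the motivation control.

## The synthetic generators

The generators are the test bed: they emulate the experimental designs
with known ground truth, and every pipeline statistic is validated against
that truth.

**Calcium imaging.** A trace is
$F(t) = F_0\,(1 + \tfrac{A}{100} K(t - t_0 - \ell)) + \varepsilon$, with
$K$ a difference-of-exponentials kernel (rise 0.2 s, decay 1.0 s —
GCaMP6s-like, a simulation default rather than a measured constant),
$\varepsilon$ i.i.d. Gaussian noise, and an optional hard ceiling applied
*after* the noise so that clipped frames have exactly zero frame
difference — the plateau signature the saturation QC detects. Amplitudes
follow a population Hill curve $A(c) = A_{max} c^h / (c^h + EC_{50}^h)$
times a per-glomerulus lognormal gain with mean 1 (meanlog
$-\sigma_{\log}^2/2$); a gain with mean above 1 would bias every
comparison against the analytic curve. Two presets encode the
concentration-coding contrast: `mature_like` ($A_{max} = 150\%$,
$EC_{50} = 0.7\%$, $h = 4$: saturated from the second ladder step) and
`immature_like` ($A_{max} = 80\%$, $EC_{50} = 5\%$, $h = 1$: graded across
the whole ladder). Population latency starts at 0.4 s and shortens by
0.1 s per ladder step, with per-glomerulus dispersion (SD 30 ms) around
it. The dispersion is there for two reasons: real latencies vary across
glomeruli, and a *deterministic* latency ladder aligns response peaks to
systematic frame phases (0.1 s steps against a 66.7 ms frame clock), which
modulates the expected extreme-value noise bias per concentration and
injects a spurious amplitude difference between concentrations of equal
true amplitude. Kernels are normalised to unit peak *on the sampling
grid*, so at zero noise the configured amplitude is recovered exactly —
the closed-loop tests depend on this. Tuning is Bernoulli per
glomerulus × odorant (default probability 0.3, a sparse panel); the blank
carries a small mechanosensory amplitude (2%).

**EPSCs.** Alpha-function currents $A\,(t/\tau)e^{1 - t/\tau}$
($\tau = 2$ ms) at 10 kHz, 10 sweeps per condition, per-sweep onset =
true onset + $\mathcal{N}(0, \sigma_\mathrm{jitter})$, Gaussian baseline
noise, per-sweep grid normalisation so a noiseless peak equals the
configured amplitude to machine precision. Condition amplitudes scale
with light intensity and duration, giving monotone power curves.

**Behavior.** Per odorant block the sniffing times are
$(t_1,\; t_1\rho,\; t_1 - J)$ plus truncated Gaussian noise, so recovered
habituation is exactly $t_1(1 - \rho)$ and dishabituation exactly $J$,
with both parameters free. Two-choice sniffing pairs are (preference ×
baseline, baseline); preference 3 sits exactly on the 0.75 threshold.
Buried-food latencies are lognormal, with the anosmic-like group centred
beyond the timeout.

Each generator consumes a single seeded stream in a fixed documented
order, so identical configuration and seed give byte-identical output;
partial regeneration is deliberately impossible rather than silently
inconsistent.

**What the generators do not emulate** — and hence what passing tests do
not certify about real data: sniff-cycle and respiration coupling of
response timing, motion and drift artifacts, correlated (shared) noise
across glomeruli, bleaching, nonlinear indicator kinetics short of the
hard ceiling, multisynaptic network contributions to evoked currents, and
any interaction between assays. Parameter recovery on this generator
demonstrates that the estimators implement their definitions correctly,
not that the definitions are robust to every artifact of in vivo data.

## Problem sizes and tolerances in the test suite

The suites run at the scale of the designs they emulate: 5 mice × 50
glomeruli × 5 odorants × 4 concentrations for the concentration contrast,
200 cells for EPSC recovery, 2000 noise-only trials for the
detection-rule cross-check, 200 matched clipped/unclipped responses for
the saturation QC, and 50 subjects for behavioral recovery. Statistical
assertions use the independent unit of each design (mice for the
mature-preset null check, glomeruli or cells for recovery bounds) at
conventional 2-SEM / 95% levels fixed in advance; exact identities
(sparseness limits, the 0.75 ratio, zero-noise closed loops) are asserted
to machine precision or to the one-frame quantisation of the latency
measure.

## Known limitations

* Calcium-response latency is threshold-based at whole-frame resolution;
  at 15 frames/s the quantisation (67 ms) is of the same order as the
  per-step latency changes being measured, which is why latency
  assertions allow one frame.
* The 3-SD responder rule applied to a max-over-window statistic has a
  substantial per-test false-positive rate (the maximum of ~45 noisy
  frames routinely exceeds 3 baseline SDs); the pipeline reproduces the
  rule as defined rather than correcting it, and the oracle-equivalence
  test quantifies it.
* The EPSC onset convention (no interpolation, first sample at/after the
  5% level) carries a deterministic half-sample expected bias plus the
  kinetic delay of reaching 5% of peak; both are inherent to the
  definition, not estimator defects.
* `normalize_to_top` silently equalises glomerulus weights but discards
  glomeruli lacking a positive top-concentration response; the two
  summaries (raw and normalised means) should be read together.
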