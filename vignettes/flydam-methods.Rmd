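---
title: "Methods: how flydam scores activity, sleep and circadian rhythmicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how flydam scores activity, sleep and circadian rhythmicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flydam)
```

This vignette documents the scientific and numerical choices behind
`flydam`: what each stage computes, where a convention had to be fixed
because the field admits more than one, and what the synthetic-data tests
do and do not establish about real recordings.

## Monitor files and validation

A DAM monitor file is a tab-delimited text file with one reading per row
and 42 fields: reading index; date (`D Mon YY`, English month
abbreviations, two-digit years mapped to 2000–2099); time (`HH:MM:SS`);
a status code; five device fields (parsed and carried through, otherwise
ignored); a light-sensor flag; and 32 beam-crossing counts, one per
channel. Timestamps are taken as written — daylight-saving shifts are not
modelled, and all internal arithmetic uses UTC so no shift can be
introduced accidentally.

Validation distinguishes recoverable from fatal defects. Status codes
outside the accepted set (default `{0, 1}`; the codes DAM hardware emits
for specific faults are not standardised, so the set is configurable)
mark a hardware-error row: the row is dropped with a warning, and —
deliberately — the surrounding timestamp grid is checked *before* the
drop, so a dropped row is never mistaken for a recording gap. True gaps
of up to 6 missing readings are repaired by inserting zero-count records
(flagged, and marked with reading index 0); longer gaps abort the read,
because binned analyses downstream would silently average over the hole.
Wrong field counts, unparseable dates, negative counts, duplicate or
decreasing timestamps and off-grid steps are always fatal. Every issue
carries the monitor id and input row, and fatal rejections attach the
full issue table to the error condition.

## Experimental days, regimes and phases

Experimental days run **light onset → next light onset**, not midnight to
midnight. This is the one convention under which "daytime activity" and
"nighttime sleep" are well defined: each LD day then contains exactly one
complete light phase followed by one complete dark phase, and the phase
partition of any full day is exact (with onset 06:00 and a 12-h
photoperiod, 720 day minutes + 720 night minutes). The same onset-anchored
boundary is kept in DD as a subjective day, since the free-running phase
of each fly is unknown. A reading's regime (LD/DD/excluded) follows from
which date range its *experimental day* falls in, so whole onset-anchored
days — never fragments — change regime. The photoperiod defaults to 12 h
but is a parameter (`day_length_hours`), because skeleton and
long/short-day designs are common.

Binning (`bin_series`) aligns bin boundaries to the light onset for the
same reason: a bin never straddles a phase boundary. Bins with fewer than
the full complement of readings (partial bins at either end of a
recording) are dropped rather than rescaled.

## Dead-fly exclusion

A fly is called dead when its total counts fall **strictly below the
threshold on any complete experimental day** (default 50 counts/day,
configurable — labs differ, and no universal value exists), and the whole
fly is then excluded from every downstream statistic. The whole-series
rule is the strictest reproducible reading of automatic exclusion; a
`truncate` mode that keeps pre-death days is provided for users who
prefer it, but it is off by default because mixing truncated and full
series changes the weighting of condition means. Partial first/last days
never trigger death calls (their totals are biased low), and a threshold
of 0 can never kill a fly. The rule is monotone by construction: raising
the threshold can only enlarge the dead set, which the tests assert over
threshold sweeps.

## Activity statistics

Aggregation is **fly-level first**: each fly is reduced to its mean daily
total (or per-bin mean) over the relevant complete days, and conditions
are then summarised as mean ± SEM *across flies*. This keeps flies with
unequal numbers of recorded days equally weighted and makes the SEM an
honest between-individual error. SEM is reported as `NA` for a single
fly rather than 0, since one individual carries no between-individual
spread.

An **activity bout** is a maximal run of consecutive readings with count
> 0 — the most common DAM convention; alternatives (e.g. maximal
non-sleep runs) exist, which is why the definition is stated here rather
than assumed. A bout belongs to the experimental day containing its first
reading and is never split at a day boundary, so bout-length statistics
are not clipped by the day grid. Bout lengths decompose exactly:
their per-day sum equals the acquisition interval times the number of
active readings, an invariant the tests check against a brute-force run
scan.

## Sleep

Sleep uses the standard fly definition: a continuous period of
inactivity lasting **at least 5 minutes**. Two formulations of the
detector exist in the literature — slide a 5-min window and mark every
all-zero window, or threshold maximal zero runs at 5 min — and they are
provably identical; the package implements the run-length form and the
test suite asserts equivalence against an independently coded sliding
window on 1,000 random traces.

Acquisition-interval handling keeps the definition exact in minutes:
sub-minute recordings are first aggregated to 1-min sums; intervals
between 1 and 5 min that divide the window are scored at native
resolution with a window of `5/interval` readings; coarser intervals are
rejected ("acquisition too coarse"), since a 10-min reading cannot
resolve a 5-min criterion. Inactivity runs touching the start or end of
the recording count if their *observed* length reaches the window — no
censoring correction is attempted, a simple rule stated here because the
alternative (discarding boundary runs) biases sleep low at both ends.
Runs crossing the LD/DD boundary are scored once on the full series and
their minutes attributed to regimes by timestamp.

## Chi-square periodogram

For each tested period of `p` bins, the binned DD series is folded into
`K = floor(N/p)` complete cycles and

`Q = K * N' * sum_h (M_h - M)^2 / sum_i (x_i - M)^2`,

with `N' = K*p` points used, `M_h` the phase means and `M` the grand
mean. Truncation to complete cycles (rather than unequal-column means
over a ragged fold) was chosen for determinism and because it is the
textbook form of the statistic; it discards at most one cycle of data
per tested period.

**Binning.** The fold requires each tested period to be a whole number of
bins. The series is therefore pre-binned to the largest width (at most
one hour) that divides every tested period and is a multiple of the
acquisition interval — 6 min for the default 18–30 h range at 0.1 h
resolution. A resolution not representable on the acquisition grid is an
error naming a usable one, rather than a silent rounding of the period
axis.

**Significance and rhythmicity.** Q is referred to the upper χ² quantile
with `p − 1` degrees of freedom. One such line is drawn for every tested
period (121 of them at the defaults), so a pointwise `1 − α` quantile
would flag pure noise as rhythmic far more often than `α`: in a
Monte-Carlo run during development, ~99% of white-noise flies crossed a
pointwise 95% line somewhere in the 18–30 h range. The default line is
therefore Šidák-corrected across the `m` tested periods,
`qchisq((1-alpha)^(1/m), p-1)`, which holds the family-wise false-rhythm
rate near `α` and matches how chi-square periodogram implementations in
this field conventionally draw their significance line; `"bonferroni"`
and pointwise `"none"` remain available. The peak is the period
maximising `Q − S` (the significance-referenced peak), with ties broken
toward the shorter period for determinism; **rhythm strength** is
`Q(peak)/S(peak)` and the rhythmicity threshold (default 1, inclusive)
partitions flies for downstream period summaries. A zero-variance series
is reported arrhythmic with strength 0 and an undefined peak instead of
erroring, so a dead-but-not-excluded channel cannot crash a batch.

Periodograms are computed on DD days when a calendar is supplied —
free-running period is a property of constant darkness — and an LD
override exists but warns, because an entrained 24-h peak reflects the
light cycle, not the clock. At least 3 cycles of the longest tested
period must be present; below that the fold has too few cycles per
column for Q's χ² reference to be meaningful.

## Actograms

Actogram matrices have one onset-anchored day per row and one
time-of-day bin per column; aggregates take the mean or median across
flies per (day, bin) cell. Double plotting concatenates day `d` with day
`d+1` in row `d` (the last row's right half is `NA`), which makes the
right half of each row identical to the left half of the next — a
redundancy the tests assert, since it is exactly what makes drifting
rhythms readable across the midnight seam.

## Synthetic data

The generator draws counts as **Poisson**(rate × interval): beam breaks
are event counts, and Poisson is the natural first model. Each fly's
rate is `max(0, baseline + amplitude·w(t))` with a square (default),
sinusoid, or crepuscular-bimodal waveform; the square wave is the
default for periodogram fixtures because its folded profile is maximally
crisp. During LD, rates are reweighted by `2f` in the day phase and
`2(1−f)` at night (`f` = `day_active_fraction`; 0.5 is neutral), and a
programmed death zeroes the rate from that day's onset. Generation is
fully deterministic under a seed (R's default Mersenne-Twister, seeded
once per monitor, channels drawn in order), to the point of
byte-identical files, and `inject_errors` corrupts a clean monitor with
a known list of defects so validator output can be checked one-for-one.

Test problem sizes were chosen as the smallest that are scientifically
meaningful rather than for coverage of every design: 6 DD days (the
shortest span giving ≥ 3 cycles over the whole 18–30 h default range),
16 flies per programmed period for recovery tests, 200 flies for the
white-noise specificity estimate, and 1,000 random traces for the sleep
dual-formulation property.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: startle responses to light
transitions, masking dynamics beyond the static day/night reweighting,
overdispersion relative to Poisson (real flies burst), position effects
along the tube, gradual death (programmed death is an instantaneous
flatline), and inter-fly correlation within a monitor. Parameter-recovery
results on synthetic data bound the pipeline's correctness, not the
biological variability of any real experiment.

## Output conventions

All exported tables are comma-separated UTF-8 with ISO-8601 dates
(monitor files keep the DAM date dialect), each with a header row, and a
rerun of the same config on the same inputs reproduces them
byte-identically — the run log echoes settings but never wall-clock
time. Plots are a thin ggplot2 layer over the exported tables; nothing
downstream depends on them.
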