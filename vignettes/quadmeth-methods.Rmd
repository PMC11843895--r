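---
title: "quadmeth: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadmeth: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadmeth)
```

quadmeth analyzes in vitro CpG-island methylation experiments in which a
PCR amplicon is enzymatically methylated by a DNA methyltransferase and
read out by single-molecule sequencing with per-read modification
probabilities. The scientific question it serves is how potential
G-quadruplex-forming sequences (PQS) inside a promoter CpG island shape
both (i) the de novo methylation pattern laid down on the two DNA strands
and (ii) the reliability of modified-base calling over G/C-rich tracts.
The package also covers the orthogonal biochemistry used in such studies:
1:1 biolayer-interferometry (BLI) binding kinetics, log-logistic IC50
inhibition curves, and methylation efficiencies from restriction-protection
assays. Because raw sequencing and instrument data are not desk-scale
inputs, first-class synthetic generators emulate them.

## Sequence model and PQS scoring

The reference object is an amplicon: an uppercase `ACGT` string, by
convention the coding (C-rich) strand. Ambiguity codes are rejected rather
than scored 0 so that malformed input surfaces immediately. Coordinates
are 0-based half-open everywhere internally; reported CpG site numbers are
produced only at output time as rank + `numbering_offset`. The packaged
752-nt promoter amplicon contains exactly 95 CG dinucleotides, so with the
default offset 3 its sites are numbered 3–97. (Two different site counts
circulate for this promoter region; the printed sequence supports 95, and
that is what the package reports.)

G4Hunter scoring: each base in a run of $k$ consecutive G scores
$+\min(k,4)$, each base in a C run scores $-\min(k,4)$, A/T score 0; the
track is the sliding-window mean (window $W$, default 25). A PQS interval
is a maximal run of consecutive same-sign windows with $|score| \ge$
threshold (default 1.2), expanded to the union of its windows. Window and
threshold defaults follow the published G4Hunter convention because the
study protocol only names the web application; both are overridable. When
expansion would make opposite-sign intervals overlap, the later interval
is clipped — a tie-break that keeps the track disjoint and sorted. A CpG
site is PQS-labeled if its C or its paired G position falls in any
interval. On the packaged amplicon this yields one G-rich interval near
the 5' end and two C-rich intervals covering CpG sites ≈51–74, matching
the study's "primary PQS region" (sites 47–72) up to the window
resolution.

## Modification calls, threshold semantics, accuracy

A call is a probability triple $(p_C, p_{5mC}, p_{5hmC})$ per read × CpG
site; triples must sum to 1 within $10^{-6}$. Template-strand (G-rich,
`-`) calls are stored against the coding-strand C position of their site,
so one `site_pos` keys both strands of a strand-symmetric site.

Two deliberately distinct code paths mirror the two analysis modes of the
upstream tooling:

* **Methylation patterns** use single-pass thresholding: the winning
  state is the argmax, retained iff its probability ≥ threshold (default
  0.65), else `filtered`; fractions are computed over retained calls only.
  Ties break canonical > 5mC > 5hmC, deterministically. Thresholds ≤ 1/3
  are rejected (every call would pass) unless explicitly overridden.
* **Calling accuracy** uses *all* calls, unfiltered:
  $\mathrm{acc} = 100\,(\bar p_C - 1/3)/(2/3)$, the linear map pinned by
  two anchors — 100% when every read is certain of canonical C, 0% when
  the three states are equiprobable. Values below 0 are reported, not
  clamped, since systematic modified-state bias at an unmethylated site is
  informative.

modBAM input decodes ML bytes as $(b + 0.5)/256$ with
$p_C = 1 - p_{5mC} - p_{5hmC}$; reverse-strand alignments map original-read
cytosines through the CIGAR to the paired G-strand site. Only positions
explicitly listed in the MM tag (the `?` semantics) produce calls.

## Region × strand statistics

The unit of replication is the CpG site: per-site percent-5mC values form
the samples, matching how strand contrasts are reported for such data;
read-level resampling is out of scope. Each region × strand cell is
summarized as mean ± SEM, and the two planned contrasts (G-rich vs C-rich,
inside and outside the primary PQS region) use Welch's unequal-variance
t-test with Welch–Satterthwaite degrees of freedom, two-tailed. p-values
are exact; "< 0.0001" formatting is display-only. The PQS region can be
defined either by a reported-site-number range (default 47–72) or from the
called PQS intervals; both are exposed because recovery tests must compare
against the labels that generated the data, while range-based definitions
match published region conventions. Sites lacking retained calls on either
strand are excluded from both strands and counted.

## Binding models

Association/dissociation follow the 1:1 Langmuir model
$R(t) = R_{eq}(1 - e^{-(k_{on}c + k_{off})t})$ with
$R_{eq} = R_{max}\,c/(c + K_d)$, then
$R(t) = R(t_a)e^{-k_{off}(t - t_a)}$; $K_d = k_{off}/k_{on}$. The fit
minimizes summed squared residuals over both phases on log-parameters
(positivity is structural), seeded analytically: $k_{off}$ from a
log-linear fit of the dissociation tail, $k_{obs}$ from the association
approach to plateau, $k_{on} = (k_{obs}-k_{off})/c$. Nelder–Mead then BFGS
polish at `reltol 1e-14`. With a single analyte concentration (the
protocol uses 690 nM, 300 s association, 120 s dissociation) $k_{on}$ and
$k_{off}$ are individually weakly identified; $K_d$ is the robust
quantity, and reported uncertainties are asymptotic (residual covariance,
delta method) — they are not claimed to match instrument-software error
bars. A flat sensorgram is a hard error, not a zero-rate fit.

Inhibition uses the two-parameter log-logistic
$f([I]) = f_0/(1 + ([I]/IC_{50})^h)$ with bottom fixed at 0 and Hill slope
fixed at 1 by default (freeable); this is the minimal standard model for a
competitive single-site inhibitor, chosen because the source protocol
names no functional form for the dose–response. Restriction-protection
methylation efficiency is $(w_0 - w_m)/w_0$; $w_0 = 0$ (uncleavable
substrate) is an error rather than a 0/0.

## The synthetic generator: what it emulates, and what a green test means

`simulate_reads()` emulates the *structure* of modification-aware
basecalls, not the sequencing physics. Per read × site:

1. truth state is 5mC with probability given by the region × strand truth
   table (5hmC never occurs in truth — it only arises as noise, mirroring
   its use as an error indicator);
2. with probability `false_mod_rate`, an unmethylated truth emits a
   confident false 5mC call;
3. otherwise the call is low-confidence with region-dependent probability
   (`p_low_conf_inside_pqs` = 0.5 vs `p_low_conf_outside` = 0.02) —
   this is the mechanism that reproduces the PQS-localized accuracy drop;
4. the emitted triple is Dirichlet: concentration 24 on the emitted state
   (0.5 elsewhere) for confident calls — mean winning probability 0.96 —
   or symmetric Dirichlet(3) for low-confidence calls, which are mostly
   removed by the 0.65 threshold and otherwise land near-uniformly on the
   three states. `Inf` concentration gives exact point masses (used by
   tests that need a deterministic emitter).

**Between-site dispersion.** Real methylation patterns vary strongly from
site to site: a reported cell mean ± 3% SEM over 26 (or 69) sites implies
a per-site SD of roughly 15 (25) percentage points. The truth table
therefore carries a per-region `site_sd` (defaults 0.15 inside the PQS
region, 0.25 outside, i.e. $0.03\sqrt{26}$ and $0.03\sqrt{69}$); the site
effect is shared between the two strands of a site (local context
modulates both strands alike), centred to mean zero within each region,
and clipped to $[0,1]$. Centring keeps cell means exactly at the
configured truth, which is what makes ±3-point recovery tests meaningful;
sharing is what lets a 2-point strand difference outside the PQS region
remain non-significant while the 25-point difference inside is highly
significant — without it, any fixed strand gap becomes significant at
enough sites, which is an artifact of an unrealistically homogeneous
truth.

**Calibration constants.** The control preset's `false_mod_rate` = 0.031
is solved from the emission model so the thresholded global 5mC of
simulated control reads is ≈ 0.04 (the observed false-positive level on
an unmethylated amplicon): with PQS site fraction $f = 25/95$, retained
fraction of low-confidence calls $r \approx 0.076$ and one third of those
landing on 5mC, $\mathrm{global\ 5mC} =
\frac{q + (1-q)\,\bar p_{low} r/3}{q + (1-q)(1-\bar p_{low} + \bar p_{low} r)}$
where $q$ is `false_mod_rate` and $\bar p_{low}$ the site-weighted
low-confidence probability; setting this to 0.04 gives $q = 0.031$. The
methylated presets use `false_mod_rate` = 0.01: the 0.04 calibration is a
property of the control arm, and carrying 0.031 into a preset whose
hypomethylated cell sits at 33% would bias that cell upward by
≈ 2.6 points, corrupting recovery tests by construction. All constants
live in `inst/extdata/presets.json`, not in code.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: basecalling from raw signal, indel/mismatch errors,
read-length and coverage variation, the quality drop at amplicon ends,
PCR bias, or true 5hmC. The dnmt3a preset encodes the published four
region × strand means *as generating truth*; recovery of 33/58/47/49 and
of the significance structure (p < 0.0001 inside, p > 0.05 outside) is
parameter recovery against that truth, **not** an independent reproduction
of the biological finding. The same applies to the BLI arm: the four
dissociation constants (65, 15, 14, 211 nM) and IC50 values (0.61 µM)
are simulation truths chosen to span the published range, and tests
establish estimator correctness (noiseless round-trips to $10^{-4}$
relative; median $|K_d|$ error < 10% at 2% noise; rank-order
preservation), not instrument agreement.

## Numerical choices and degenerate inputs

* argmax ties: canonical > 5mC > 5hmC, fixed.
* classification threshold domain (1/3, 1]; lower only by explicit
  override.
* Welch test requires n ≥ 2 per sample and non-zero pooled variance;
  identical samples with spread give t = 0, p = 1.
* optimizer tolerances: `reltol 1e-14`, two-stage NM → BFGS; fits flagged
  `converged`.
* empty CpG index is legal (a CpG-free control oligo is a real input);
  an empty pileup writes a header-only table that round-trips.
* simulators are pure functions of (configuration, seed); identical seeds
  produce byte-identical call tables, and the pipeline manifest embeds the
  configuration hash and seed so reruns are byte-reproducible.

## Scaling notes for the test suite

Property suites run at reduced but stated scale: null calibration of the
within-PQS contrast uses 1000 replicates on a 30-site synthetic amplicon
at 50 reads/strand with the point-mass emitter (the quantity under test is
the calibration of the contrast pipeline, which does not depend on
amplicon scale); convergence-to-truth runs at 2000 reads/strand on the
full amplicon and asserts cell means within ±1.5 points (per-site
assertions at that depth would be dominated by binomial noise across 190
site × strand cells).

## Known limitations

Single-concentration BLI cannot separate $k_{on}$ and $k_{off}$ sharply;
no mass-transport or bivalent models. No multiple-testing correction (two
planned contrasts). The generator's noise family is Dirichlet by
construction, not a fit to empirical probability distributions, so
accuracy *values* inside PQS (≈ 45% at the defaults) reproduce the
qualitative dip, not published figure values. modBAM support covers the
explicit-skip (`?`) MM convention only.
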