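---
title: "Collision-energy optimization for tryptic and nontryptic digests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision-energy optimization for tryptic and nontryptic digests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceopt)
```

## The problem

In bottom-up proteomics, peptides produced by enzymatic digestion are
fragmented by collision-induced dissociation (CID), and the collision
energy (CE) applied to each precursor controls how informative the MS/MS
spectrum is. Instrument methods ramp CE linearly with precursor m/z, with
a separate line per charge state, but those defaults were historically
tuned on tryptic digests. Tryptic (and Arg-C) peptides carry a basic
residue (Lys/Arg) at the C-terminus that stabilizes the y-ion series;
peptides from Glu-C, Asp-N, and chymotrypsin do not, their b- and y-ions
behave comparably, and they fragment optimally at substantially lower
energies. `ceopt` implements the analysis that quantifies this: it turns
per-run peptide-spectrum-match (PSM) score tables acquired over a grid of
CE offsets into per-peptide optimal energies, per-charge linear CE(m/z)
settings per enzyme class, normalized b/y fragment-ion statistics, and
performance metrics for competing CE methods.

## The model

For each peptide ion (sequence × charge), the best search-engine score at
every acquired CE offset forms a score series. After max-normalization,
the series is modelled as a one- or two-component Gaussian in the offset
$x$ (eV):

$$ s(x) = \sum_{i=1}^{k} A_i \exp\!\left(-\frac{(x-\mu_i)^2}{2\sigma_i^2}\right), \qquad k \in \{1, 2\}, $$

with no baseline term: an offset at which the peptide was not identified
contributes no data point, not a zero. The fitted centers $\mu_i$ are the
peptide's optimal CE offsets. Peptides whose score curve shows a single
maximum are *unimodal*; curves with two maxima are *bimodal*, reflecting
the different energy dependence of the b- and y-ion series. Per enzyme,
the optima of doubly and triply charged peptides are regressed on
precursor m/z by ordinary least squares, giving deployable per-charge
lines. For trypsin and Arg-C the line through the unimodal optima is the
deployed setting; for Glu-C, Asp-N, and chymotrypsin the unimodal and the
lower-energy bimodal optima are pooled, because those two point clouds
nearly coincide for these enzymes.

## Pipeline and interfaces

The stages are `simulate` → `series` → `fit` → `trend` → `fragstats` →
`perf` → `report`, orchestrated by `run_stage()` / `run_pipeline()`;
every stage communicates only through TSV/FASTA/YAML files, so any stage
can be rerun from serialized outputs. A thin command-line wrapper over
these functions ships in `inst/cli/ceopt.R`. Offsets (eV relative to the
reference line), not absolute energies, are the canonical x-axis of all
intermediate files; absolute eV appears only in trend outputs and
reports, which keeps the reference method a single source of truth.

## Inclusion filters

Only confidently and repeatedly identified ions enter the fits. The
defaults reproduce standard engine-specific criteria: a Mascot series
must exceed score 15 at six or more *adjacent* grid offsets and exceed 25
at least once; Byonic analogously with 100 and 300. Minimum peptide
length is 6 and singly charged species are excluded (they fragment
poorly and are often not peptides). Design choices worth knowing:

* "identified at an offset" means *strictly* greater than the floor
  score, and the peak criterion is strict too, for consistency;
* "adjacent" means consecutive offsets of the acquisition grid — one
  missing grid point breaks the run;
* duplicate PSMs at an offset collapse to their maximum score (the best
  spectrum represents identifiability);
* charges ≥ 4 pass the filter but are excluded later from trend fitting,
  where only charges 2 and 3 are used.

## Numerical choices in the fit

Fitting is Levenberg–Marquardt least squares (`minpack.lm`), with
deterministic, grid-aware multi-start initialization: for $k=1$ the
argmax point and the intensity-weighted mean; for $k=2$ the two highest
local maxima, falling back to grid tertiles. Width starts at 5 eV and is
bounded to [1, 40] eV; centers are constrained to one grid step beyond
the acquired range, and any fit whose center lands outside the grid
proper is *edge-flagged* — a boundary center is censored, not estimated,
so edge-flagged fits never enter trend fitting. Non-convergence of every
start raises a classed error; `fit_series()` then returns `NULL` for
that ion rather than poisoning the table. All-zero series are rejected
at normalization.

## The modality decision

The data define unimodal/bimodal by the number of curve maxima, but a
finite noisy sample needs a decision rule. Ours accepts the
two-component fit only when it is a real, resolvable second peak: both
amplitudes ≥ 0.25 (normalized scale), centers ≥ 4 eV apart (two grid
steps), and a nested-model F-ratio test at level α confirming the extra
component earns its three parameters. The default α is 0.01 rather than
the conventional 0.05: on genuinely unimodal curves the test's nominal
level *is* the false-bimodal rate, and we want misclassification rare in
both directions; at 0.01 we measure ~100% correct calls on
well-separated two-peak constructions and ~98% on single-peak
constructions (these rates are computed in the test suite). All four
constants are exposed in `modality_criteria()`. An exact amplitude tie
in a bimodal fit resolves the "taller" peak to the lower-energy one,
consistent with the downstream preference for the lower optimum.

## What the synthetic generator emulates

`synthetic_config()` + `simulate_series()` produce a complete
experiment — proteome, digest, PSM tables across the 21-point grid,
fragment annotations — plus ground truth for every simulated ion, which
is what makes every stage testable by parameter recovery. The defaults
describe the study conditions the package targets:

* 21 offsets from −20 to +20 eV in 2 eV steps; 5 eV instrument floor;
* per-peptide optimum offsets scatter around the enzyme class's shift
  with 2 eV jitter; the alternative class (Glu-C, Asp-N, chymotrypsin)
  sits 10 eV below the tryptic reference — within the 5–15 eV range such
  digests show in practice, and about 20% of a typical tryptic setting;
* 30% of ions are bimodal, with peak separation ~N(12, 2) eV and the
  lower-energy peak taller with probability 0.85;
* score-curve widths are ~N(5, 1) eV truncated to [3, 10] — the scale at
  which two peaks 12 eV apart are genuinely resolvable;
* peak raw scores are log-normal (median 150 on the Mascot scale) so
  normalization is exercised over an order of magnitude; multiplicative
  noise sd 0.1; detection floor 15;
* fragment annotations encode C-terminal basic-residue stabilization:
  peptides ending in K/R have y-ions dominating b-ions (2.5-fold) with
  the detectability apex at offset 0, other peptides have comparable b/y
  with the apex shifted to −9 eV (within the 8–10 eV shift such digests
  show).

One subtlety is enforced by construction: a drawn two-component ion is
only labelled bimodal if its noiseless mixture actually has two local
maxima. Heavily overlapping components produce a single-maximum
"shoulder" curve, which is unimodal by definition; labelling it bimodal
would make the ground truth unrecoverable in principle. Separation draws
are therefore rejection-sampled against the two-maxima condition (with a
4σ fallback).

What the generator does **not** emulate: retention time and elution
profiles, isotope envelopes and chimeric spectra, FDR-calibrated decoys,
charge-dependent voltage granularity of the instrument, engine-specific
score distributions beyond a scale, and real sequence-dependent
fragmentation chemistry beyond the basicity grouping. Passing recovery
tests therefore demonstrates the *analysis* is correct and well-calibrated
under its stated assumptions, not that those assumptions exhaust real
LC-MS/MS data.

## Trend stage conventions

* Absolute optima are reference-line value plus fitted offset; values
  below the instrument floor are flagged, not clamped, in reporting.
* OLS (not robust regression) is used for the lines, as is conventional
  for these plots; `residual_sd` is reported so outlier influence is
  visible.
* Class comparison evaluates both lines over m/z 300–1300 (101 points)
  and reports the mean difference in eV and as percent of the tryptic
  setting, per charge and pooled as the unweighted mean of charges 2
  and 3.
* Basicity grouping: `CTERM_BASIC` requires K/R at the C-terminus
  (mirroring tryptic/Arg-C termini); histidine counts as basic only for
  the internal/no-basic split. Both residue sets are overridable.
* eV↔NCE% conversion constants are instrument-specific vendor values;
  they are explicit configuration (`nce_params()`) with commonly cited
  defaults (reference m/z 500; factors 1.0/0.9/0.85/0.8 for z = 1–4),
  not buried constants.

## Performance metrics

Peptide acceptance in performance tests is strict (Mascot score > 25;
Byonic score > 200 *and* log Prob > 2) with charges merged to sequence
level. Sequence coverage is the conventional identified/total fraction —
the union of accepted peptide intervals over the protein length — and
the comparison is restricted to proteins identified at least once by
both methods, averaged per run and then over repetitions. Peptide-level
winners compare per-method mean scores across repetitions (a max-based
variant is available); exact ties count for neither side and are
reported separately. Ambiguous peptides matching several positions or
proteins contribute every occurrence to coverage.

## Problem sizes and determinism

The test suite and the acceptance script run the generator at its
default scale (12 proteins of mean length 350, giving roughly 700–1100
accepted ions per enzyme and ≥ 150 trend points per charge), which keeps
a full simulate–fit–trend cycle under a minute while leaving enough
statistics for 3-standard-error recovery checks; stochastic checks use
fixed seeds and 3σ binomial bands. Every simulation is a pure function
of its config, including the seed, so reruns are byte-identical.

## Known limitations

* Bimodal ions misclassified as unimodal (mostly weakly resolved ones)
  contribute a center between their two peaks; this biases the
  tryptic-class unimodal trend intercept upward by a fraction of an eV
  at the default conditions. The same contamination affects any
  analysis of this design on real data.
* The observed lower-taller fraction among *classified* bimodal fits is
  slightly below the generating probability, because ions whose second
  peak is small or partly below the detection floor are harder to call
  bimodal (detection bias).
* Semi-specific or nonspecific digestion, PTM-aware masses, and a/x/c/z
  or internal fragment ions are out of scope.
* The chymotrypsin definition cleaves C-terminal of A, D, E, L, M, F,
  Y, W with no proline suppression — broader than the common
  F/Y/W/L(/M) rule; results for chymotrypsin should be read with that
  definition in mind.
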