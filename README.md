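# ceopt

Collision-energy optimization for tryptic and nontryptic bottom-up
proteomics.

## What this package is for

In collision-induced dissociation (CID), the collision energy (CE)
applied to a peptide precursor is the main knob controlling MS/MS
spectrum quality, and instruments ramp it linearly with precursor m/z
per charge state. Those default ramps were tuned on tryptic digests.
Peptides from the "alternative" proteases Glu-C, Asp-N, and
chymotrypsin lack the basic C-terminal residue that stabilizes y-ions
in tryptic and Arg-C peptides, and they fragment optimally at markedly
lower energies. `ceopt` is for mass spectrometrists and proteomics
bioinformaticians who want to derive, compare, and validate
enzyme-class-specific CE methods from energy-dependent measurement
series — and for anyone who needs a fully ground-truthed synthetic
test-bed for such an analysis.

## The analysis in brief

From PSM score tables acquired at CE offsets −20…+20 eV (2 eV steps, 21
runs) relative to a reference linear CE(m/z) method:

1. **Series building** — per (peptide, charge) ion, the best engine
   score at each offset; engine-specific inclusion filters (Mascot:
   score > 15 at ≥ 6 adjacent offsets, > 25 at least once; Byonic: 100 /
   300; length ≥ 6; charge ≥ 2).
2. **Peak fitting** — max-normalized series fitted with
   `s(x) = Σᵢ Aᵢ exp(−(x−μᵢ)²/2σᵢ²)`, k = 1 and 2, by
   Levenberg–Marquardt; an F-ratio test plus amplitude and separation
   floors decide unimodal vs bimodal; the centers μᵢ are the per-peptide
   optimal CE offsets.
3. **Trend fitting** — optima of 2+ and 3+ ions regressed on m/z per
   enzyme class (trypsin/Arg-C: unimodal optima; Glu-C/Asp-N/
   chymotrypsin: unimodal + lower bimodal optima), yielding deployable
   per-charge lines `CE = a·mz + b` with a 5 eV instrument floor, plus
   eV ↔ NCE% conversion.
4. **Fragment statistics** — normalized b/y ion counts (per L−1) and
   intensities (per precursor intensity) averaged per CE shift, and the
   offsets at which those curves peak.
5. **Performance testing** — two CE methods compared by accepted-peptide
   hit gain, protein sequence coverage (union of identified intervals),
   and peptide-level score winner fractions over repeated runs.

A seedable synthetic-experiment generator (`synthetic_config()`,
`simulate_series()`, `simulate_performance_experiment()`) produces
proteome, digest, PSM tables, fragment annotations, and the ground
truth for every stage, covering five enzyme specificities (trypsin,
Arg-C, Glu-C, Asp-N, chymotrypsin) with in-silico digestion and
monoisotopic m/z computation built in (`digest()`, `peptide_mz()`).

## Worked example

Simulate an energy-dependent series for a tryptic and a Glu-C digest,
run the analysis, and compare the fitted class settings:

```r
library(ceopt)
ref <- default_reference_method()

analyse <- function(enzyme, seed) {
  cfg <- synthetic_config(enzyme = enzyme, n_proteins = 6, seed = seed)
  sim <- simulate_series(cfg)
  accepted <- filter_series(build_series(sim$psms), filter_params("MASCOT"))
  fits <- fit_all_series(accepted)
  points <- select_points(optimum_points(fits, ref, enzyme))
  list(fits = fits, trends = fit_trends(points))
}

tryp <- analyse("trypsin", seed = 11)
gluc <- analyse("glu_c",  seed = 12)

print(tryp$trends[["2"]])
print(gluc$trends[["2"]])
cmp <- compare_classes(tryp$trends[["2"]], gluc$trends[["2"]])
cat(sprintf("Glu-C fragments %.1f eV below the tryptic setting (%.1f%% lower)\n",
            cmp$mean_delta_ev, cmp$percent_lower))
cat(sprintf("bimodal Glu-C peptides with taller lower-energy peak: %.0f%%\n",
            100 * fraction_lower_taller(gluc$fits)))
```

which prints:

```
<trend_line> trypsin z=2: CE = 0.04978 * mz + 10.38 (n=181, sd 2.51)
<trend_line> glu_c z=2: CE = 0.05056 * mz + -0.7479 (n=292, sd 2.22)
Glu-C fragments 10.5 eV below the tryptic setting (23.1% lower)
bimodal Glu-C peptides with taller lower-energy peak: 83%
```

The fitted doubly-charged trend lines recover the generator's reference
slope (0.05 eV/Th) and the −10 eV class shift of the alternative-enzyme
digest (about 20% of a typical tryptic setting over m/z 300–1300), and
most bimodal peptides score best at their lower-energy optimum.
`build_method()` turns fitted trends into a deployable method;
`method_nce_range()` expresses it on the vendor NCE% scale.

The same stages are available as a file-based pipeline
(`run_pipeline(pipeline_config(...), outdir)`, or stage by stage via
`run_stage()`), with a thin command-line wrapper in
`inst/cli/ceopt.R`:

```sh
Rscript inst/cli/ceopt.R all --seed 3 --outdir ceopt_out --enzymes trypsin,glu_c
```

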