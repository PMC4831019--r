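# cardiosplice

From a cardiac sodium-channel splicing switch to conduction delay — as one
tested, reproducible analysis chain.

In myotonic dystrophy (DM), expanded CUG repeats sequester MBNL splicing
factors, and the cardiac sodium-channel gene *SCN5A* partly reverts from its
adult exon 6B to the mutually exclusive fetal exon 6A. The fetal channel
isoform activates ~7 mV more depolarised and carries ~45% less peak current
(an equimolar mix: +3.8 mV, −30%), with steady-state inactivation and
recovery unchanged. `cardiosplice` implements the full computational chain
that connects that molecular switch to cardiac conduction delay:

* **synthetic data** for every input: two-electrode voltage-clamp current
  families (Hodgkin–Huxley m³h forward model), EMSA binding curves, exon
  cohorts with intronic flanks and planted motifs (FASTA/BED), BstBI-digest
  gel band tables, qPCR Ct tables;
* **biophysics fitting**: Boltzmann steady-state activation
  `m∞ = 1/(1+exp(−(V−Vm)/s))` and inactivation, inactivation time constants,
  recovery, Hill binding curves
  `y = min + (max−min)/(1+(x/IC50)^(−n_H))`, variant comparisons with
  Student *t*;
* **motif enrichment**: strand-aware window extraction, 4-mer counting, an
  exact one-sided binomial test of misregulated-exon windows against 2,000
  control exons, and YGC (CGC/UGC, the MBNL element) classification;
* **splicing quantification**: restriction-digest simulation (TT^CGAA),
  percent-spliced-in from length-corrected band intensities, 2^−ΔCt
  expression, group statistics and PSI–ECG correlation;
* **cardiac simulation** (Rcpp): a 1D Endo/M/Epi transmural monodomain
  wedge with unipolar pseudo-ECG and QRS measurement, and an
  atrium–AV-node–His strand reporting the atrium–His (AH) interval, both
  parameterised directly by the fitted channel variants.

## Worked example

Generate noise-free clamp families for the adult and fetal presets, fit
steady-state activation, and compare — the full generate → fit → compare
chain:

```r
library(cardiosplice)

proto <- clamp_protocol()                    # −120 mV holding, −80…+20 mV steps
ext   <- clamp_protocol(test_potentials = seq(-80, 80, 10))
erev  <- iv_and_reversal(gen_clamp_family(channel_preset("adult"), ext))$erev

adult <- gen_clamp_family(channel_preset("adult"), proto, noise_sd = 0)
fetal <- gen_clamp_family(channel_preset("fetal"), proto, noise_sd = 0)
compare_variants(adult, fetal, erev = erev)
#> <variant_comparison>  dV1/2(act) = +6.99 mV, peak reduction = 45.0% at -10 mV
```

The +7 mV depolarising activation shift and the 45% peak-current reduction
are the electrophysiological signature of the fetal exon-6A channel. Feed
the same presets into the tissue models:

```r
w     <- wedge_config()                      # 0.12/0.65/0.24 cm, 2×GNa, 1 Hz
adult <- simulate_wedge(w, "adult")
fetal <- simulate_wedge(w, "fetal", calibration = adult$calibration)
c(adult$qrs$qrs_duration, fetal$qrs$qrs_duration)
#> [1] 65.5 97.0        # ms: the switch widens the QRS complex

run_av_strand("fetal")
#> <av_result 'fetal'>  AH = 148.6 ms (atrial 2.3 -> His 150.9, CL 350 ms)
```

The adult strand gives an AH near 77 ms, so the fetal variant roughly
doubles atrio-ventricular conduction time — slowed ventricular
depolarisation and AV conduction from a single splicing change.

The whole chain (clamp fits, EMSA fits, motif map, PSI statistics, qPCR,
simulations) runs as one pipeline with per-stage derived seeds and a
manifest:

```r
res <- run_pipeline(default_pipeline_config(seed = 1))
print(res)
```

or from a shell: `Rscript inst/cli/pipeline.R --seed 1 --outdir run1`.

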