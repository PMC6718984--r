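# cimquant

Quantification of cell polarity, infiltration and subcellular marker
localization for glioma invasion assays.

Glioma cells that retain contact inhibition of migration (CIM) polarize
toward a scratch wound — the Golgi repositions between the nucleus and the
free space — while cells that have lost CIM migrate in any direction and
infiltrate brain tissue. `cimquant` provides tested, reusable
implementations of the three quantifications such studies rely on, for
researchers analysing scratch assays, orthotopic transplant sections, or
immunofluorescence localization:

1. **Scratch-assay polarity.** Each cell's migration direction is the
   nucleus→Golgi vector, measured as a signed angle θ against the
   wound-directed rim normal; cells with |θ| ≤ 60° are polarized. Under
   uniform directions the sector captures 1/3 of cells, so bias is tested
   with a two-class chi-squared goodness of fit,
   χ² = (O_p − n/3)²/(n/3) + (O_np − 2n/3)²/(2n/3), df = 1, with power at
   Cohen's effect size w from the noncentral chi-squared (ncp = n·w²).
2. **Infiltration enrichment.** Distances of two mixed cell populations
   (silenced vs control) from an injection-site rim, normalized per section
   into 10 bins of its own maximum distance, pooled counts per bin, the
   silenced/control ratio per bin, and a Pearson trend test of ratio vs
   bin index; plus tumor composition (silenced fraction) over days post
   injection.
3. **Compartment fractions.** Marker signal partitioned into nuclear,
   perinuclear (3 µm sub-pixel EDT band) and cytoplasmic/membrane fractions
   that sum to 1, with Welch comparisons between conditions.

Every stage has a seed-deterministic synthetic-data generator with known
ground truth (`gen_scratch_field()`, `gen_section()`,
`gen_compartment_image()`, `gen_timecourse()`), so correctness is
verifiable by parameter recovery. Thin helpers cover 2^−ΔΔCt qPCR
quantification and densitometry normalization.

## Worked example

Generate a half-polarized scratch field and score it:

```r
library(cimquant)
field <- gen_scratch_field(800, polarized_weight = 0.5, seed = 42)
res <- polarity_analysis(field, band_um = 150)
res
#> Polarity test: 527 / 800 polarized (expected 266.7 under null)
#>   chi-squared = 381.226, df = 1, p = 6.732e-85
res$power
#> [1] 0.8074304
```

With mixture weight ρ = 0.5 the expected polarized fraction is
ρ + (1−ρ)/3 = 2/3; the analysis recovers 527/800 = 0.659 and rejects the
uniform sector null decisively. `res$power` is the test's power at the
configured effect size (w = 0.1) for this n.

Infiltration with differential spatial decay of the silenced population:

```r
secs <- lapply(1:4, function(i)
  gen_section(970, 352, decay_silenced = 0.02, decay_control = 0.005,
              seed = i, section_id = paste0("S", i)))
enrichment_profile(secs)
#> Bin enrichment over 4 sections (3880 silenced, 1408 control cells)
#>   ratio per bin: 6.99 4.45 2.78 2.03 1.13 0.656 0.5 0.384 0.159 0.143
#>   Pearson r = -0.885 (|r| = 0.885), p = 0.0006589 over 10 defined bins
```

The silenced population is enriched near the rim and depleted far from it;
the negative ratio-vs-bin correlation quantifies its reduced infiltration.

Compartment fractions from a synthetic two-channel image with 5% noise:

```r
img <- gen_compartment_image(target_fractions = c(0.2, 0.3, 0.5),
                             noise_sd = 0.05, seed = 9)
compartment_fractions(img)
#> Compartment fractions (band 3.0 um, otsu threshold):
#>   nuclear 0.200 | perinuclear 0.300 | cytoplasmic/membrane 0.500
```

A command-line wrapper over the same functions is installed at
`system.file("cli/cimquant.R", package = "cimquant")` with subcommands
`simulate`, `polarity`, `infiltrate`, `composition` and `express`; every
run writes a JSON manifest recording inputs, seed and package version.

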