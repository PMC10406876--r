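# iccscoloc

Quantifying whether two fluorescently labelled nuclear species occupy the
same sites — for example a chromatin-associated protein and a histone
modification imaged in two confocal channels — is a routine need in nuclear
organisation studies. Pixel-based coefficients (Pearson, Manders) degrade
when foci are dense, and object-based matching requires segmenting every
focus. `iccscoloc` implements the alternative: **image cross-correlation
spectroscopy (ICCS)**, the spatial variant of fluorescence (cross-)
correlation spectroscopy, which extracts a *colocalized fraction* from the
amplitudes of spatial intensity-fluctuation correlation functions and is by
construction independent of foci density. The package also counts discrete
**proximity ligation assay (PLA)** puncta in confocal z-stacks, compares
per-cell measurements across groups with the matching statistical
procedure, and ships a seeded synthetic-image generator so every estimator
can be validated against known ground truth.

## The estimator

For channels *i, j* the masked 2D correlation function is

    G_ij(dx, dy) = <I_i(x, y) I_j(x + dx, y + dy)> / (<I_i> <I_j>) - 1

with all averages over pixel pairs whose endpoints both lie inside the
nuclear mask (for *i = j* this is the image autocorrelation; for *i ≠ j*
the cross-correlation). Each 2D function is reduced to a radial profile by
an angular mean and fitted with

    G_ij(r) = G_ij(0) exp(-r^2 / w_ij^2) + G_ij(inf)

The colocalized fraction is the amplitude ratio

    f = [ G_12(0)/G_22(0) + G_12(0)/G_11(0) ] / 2

Because each autocorrelation amplitude scales inversely with the number of
particles N_i in the observation area and the cross amplitude scales with
N_12 / (N_1 N_2), `f` estimates the fraction of particles present in both
channels and does not change with foci density.

PLA puncta are counted per cell by thresholding a z-stack (fixed value or
global Otsu), 26-connected 3D component labelling and a minimum-volume
filter. Groups are compared with one-way ANOVA followed by all pairwise
two-sample t-tests, each preceded by an F-test of variance equality that
selects the pooled or Welch variant, with significance declared at the
Bonferroni-corrected level (0.05/3 ≈ 0.0167 for three groups).

## Worked example

```r
library(iccscoloc)

# a synthetic nucleus: 50 foci/channel, half of them colocalized
sim <- simulate_two_channel(foci_sim_params(f_true = 0.5, seed = 1))
mask <- nuclear_mask(sim$truth$nucleus_mask_true)
res <- run_iccs(sim$image, 1, 2, mask)
res
#> <iccs_result> f = 0.4098 (raw 0.4098)
#>   g0: 11 = 1.201, 22 = 1.086, 12 = 0.4675
```

The cross-correlation amplitude is roughly 40% of the autocorrelation
amplitudes, so the amplitude ratio recovers the planted fraction 0.5 to
within the single-image simulation noise (averaging over cells tightens
it; see the acceptance report).

```r
# PLA counting on a synthetic stack with 15 planted puncta
st <- simulate_pla_stack(n_spots = 15, seed = 1)
count_spots(st$stack)$count
#> [1] 15

# group comparison at the published cohort parameters
coh <- simulate_cohort(cohort_preset_h3k9ac(), seed = 1)
gs <- split(coh$pla_count, coh$group)
compare_groups(lapply(names(gs), function(nm) group_sample(nm, gs[[nm]])))
#> <comparison_report> ANOVA F = 61.34, p = 6.146e-15; alpha_bonf = 0.01667
#>   group_a    group_b variance_F_p     t_variant      t_stat          t_p significant
#> 1  MCF10A       MCF7    0.1625697 homoscedastic   0.1230189 9.027405e-01       FALSE
#> 2  MCF10A MDA-MB-231    0.9490177 homoscedastic  -8.7497829 1.218494e-10        TRUE
#> 3    MCF7 MDA-MB-231    0.1821727 homoscedastic -10.1862010 2.039409e-12        TRUE
```

Only the invasive line differs from the other two — the published
significance pattern.

The command-line driver runs whole pipelines from a JSON config
(`inst/exec/iccs-coloc run --config cfg.json --out-dir out`), writing
`cells.csv`, `comparisons.csv` and `run.log`; identical config and seed
reproduce the CSVs byte for byte.

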