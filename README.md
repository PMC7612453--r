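# foldstab

Site-specific protein fold-stability analysis from 2D NMR peak volumes.

Most stability measurements (CD, calorimetry, fluorescence) yield one
global denaturation curve and presume an all-or-none unfolding event. A
temperature series of ¹⁵N-HSQC spectra instead gives one melting curve per
backbone amide. For proteins that unfold both on heating and on cooling
above 0 °C — yeast frataxin (Yfh1) at low ionic strength is the model
system — each residue's peak-volume series yields a full per-residue
*stability curve*, and residues that disagree with the buried-core
consensus carry information about how cold and heat denaturation differ
mechanistically. `foldstab` is for NMR spectroscopists and protein
biophysicists who want to run this analysis on their own temperature
series, or to simulate how NMR artefacts distort apparent stability.

## The model

Two-state unfolding with temperature-independent ΔCp, free energy by the
modified Gibbs–Helmholtz equation (ΔG = G_U − G_F, kcal/mol, Kelvin
throughout):

    ΔG(T) = ΔHm (1 − T/Tm) + ΔCp [(T − Tm) − T ln(T/Tm)]

with zeros at the cold-denaturation temperature Tc and the melting
temperature Tm, maximum at the zero-entropy temperature
Ts = Tm·exp[−ΔHm/(Tm·ΔCp)], and curvature −ΔCp/T. Unfolded populations
are Boltzmann, f_U = e^(−ΔG/RT)/(1 + e^(−ΔG/RT)). Per residue, the
pipeline is:

1. normalise peak volumes by a same-temperature reference peak;
2. convert to folded populations via f = (V − V_U)/(V_F − V_U), with the
   unfolded baseline V_U taken at the top grid temperature, and anchor to
   a known folded fraction at room temperature (70% for Yfh1);
3. fit (ΔHm, Tm, ΔCp) by Levenberg–Marquardt least squares on the
   populations (top temperature excluded; unphysical or non-convergent
   fits flagged), with error bands from covariance propagation;
4. score burial of each amide nitrogen as RAD = D × RA × 100 (exteriority
   × relative accessibility) from a PDB structure, or take a precomputed
   table; residues with RAD < 0.1 define the buried-core reference curve;
5. classify every residue by ΔTm/ΔTc against the reference (consistent
   < 1.5 K, outlier > 3 K on the mean absolute shift) and decompose the
   difference into the three classic thermostability mechanisms (raise
   ΔHs / lower ΔCp / translate the curve).

A synthetic-data module generates volume series with known ground truth
plus the three artefact mechanisms (exchange broadening during INEPT,
differential relaxation, solvent hydrogen exchange), used to show that the
temperature of maximum stability Ts is robust to artefacts that visibly
distort Tm and Tc.

## Worked example

Published parameters of a buried leucine of Yfh1, and the 11 buried-core
reporters selected by the RAD threshold:

```r
library(foldstab)

thermo_params(28.5, 298.2, 3.73)
#> Two-state stability parameters (dG = G_U - G_F, kcal/mol)
#>   dHm = 28.5 kcal/mol   Tm = 298.2 K   dCp = 3.73 kcal/mol/K
#>   dSm = 0.09557 kcal/mol/K   Ts = 290.7 K   dHs = 0.362 kcal/mol   Tc = 283.2 K

select_by_rad(yfh1_thermo_table(), 0.1)
#>  [1] "88 Leu"  "130 Ile" "131 Trp" "132 Leu" "142 Phe" "150 Val" "151 Ser"
#>  [8] "158 Leu" "159 Thr" "161 Ile" "166 Val"
```

The derived numbers mean: the residue's curve crosses zero at 283.2 K
(cold denaturation) and 298.2 K (heat melting), is maximally stable at
290.7 K where the folded state is favoured by only 0.36 kcal/mol — the
marginal stability characteristic of Yfh1 without salt.

Simulate one noisy melting series from those parameters and fit it back
through the full pipeline:

```r
p <- thermo_params(28.5, 298.2, 3.73)
spec <- synthetic_spec(p, noise_sigma = 0.03, seed = 42)
gen <- generate_series(spec, residue_label = "70 Leu")
summary(fit_generated(gen, spec))
#> Residue: 70 Leu
#>     Estimate Std. Error
#> dHm  26.1541     0.8089
#> Tm  297.6492     0.1398
#> dCp   3.7222     0.0901
#> Derived:  dSm =   0.087869, Ts = 290.705023, dHs =   0.306288, Tc = 283.815722
#> n = 14, RMS residual = 1.065e-02
```

With 3% volume noise the melting and cold-denaturation temperatures come
back within fractions of a Kelvin (Tm 297.6 vs 298.2, Tc 283.8 vs 283.2),
and Ts is essentially exact — the robustness property the simulation
module exists to demonstrate. `plot(fit)` draws the stability curve with
its grey one-sigma band and the three characteristic temperatures.

For a full dataset: `run_fit()`, `run_classify()` and `run_simulate()`
drive the pipeline from a single `run_config()` (JSON-serialisable), read
delimited volume tables, and write Table-style TSV outputs with explicit
units. See the vignette in `vignettes/site-specific-stability.Rmd` for the
model, the design decisions and the known limitations.

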