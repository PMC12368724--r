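# SECdimer

Quantifying protein homodimer dissociation from size-exclusion
chromatography (SEC) dilution series.

Many proteins — among them GH1 β-glucosidases such as the *Spodoptera
frugiperda* enzyme whose homodimer motivated this package — populate a
reversible monomer–dimer equilibrium

    M + M ⇌ D,    K_D = [M]² / [D]

whose dissociation constant sets how much dimer exists at a working
concentration. SECdimer is for biochemists who measure that equilibrium
by SEC: load a dilution series, integrate the monomer and dimer peaks,
convert areas to concentrations with the mass balance
`c_total = [M] + 2[D]`, and estimate K_D from the linearized relation

    [M]² = K_D · [D]

— a line through the origin in the ([D], [M]²) plane whose slope is K_D.
The package covers the full workflow:

* **Simulation** — synthetic two-peak chromatograms whose areas follow
  the equilibrium at a chosen true K_D (`simulateDilutionSeries()`), and
  Michaelis–Menten product time courses (`simulateTimecourse()`), so the
  whole pipeline is testable end to end.
* **Chromatography** — CSV read/write, linear baseline correction,
  trapezoidal peak integration over fixed windows
  (`readChromatogram()`, `subtractBaseline()`, `quantifySpeciesPeaks()`).
* **Equilibrium** — areas → species concentrations
  (`speciesFromAreas()`), through-origin and free-intercept linear fits
  (`fitKdLinear()`), a direct nonlinear dimer-fraction fit
  (`fitKdNonlinear()`), and case-resampling bootstrap CIs
  (`bootstrapKd()`).
* **Thermodynamics** — ΔΔG⁰ of dissociation between variants,
  `ΔΔG = RT ln(K_D,variant / K_D,reference)` (positive = destabilized
  dimer), hydrogen-bond and buried-apolar-surface energy budgets, and
  phosphate-buffer ionic strength (`ddgDissociation()`, `ddgTable()`,
  `hbondEnergyBudget()`, `hydrophobicEnergy()`,
  `phosphateIonicStrength()`).
* **Interface analysis** — a deterministic Shrake–Rupley SASA
  implementation, per-residue buried-area differencing between isolated
  chains and the complex, polarity classification and distance-based
  inter-chain hydrogen-bond detection (`shrakeRupleySasa()`,
  `interfaceResidues()`, `detectHbonds()`, `classifyPolarity()`).
* **Kinetics** — initial rates from product time courses and direct
  nonlinear Michaelis–Menten fitting with error propagation
  (`initialRates()`, `fitMichaelisMenten()`, `relativeEfficiency()`).

## Worked example

Simulate a 12-sample dilution series (1–100 µM) for a dimer with true
K_D = 7 µM and 1% area noise, then run the full quantification pipeline
and bootstrap the estimate:

```r
library(SECdimer)

chroms <- simulateDilutionSeries(trueKd = 7,
                                 cTotals = 10^seq(0, 2, length.out = 12),
                                 noiseCv = 0.01, seed = 42)
species <- speciesFromChromatograms(chroms)
bootstrapKd(species, nBoot = 1000, seed = 42)
#> Dimer dissociation fit (linear-origin)
#>   K_D = 6.905 uM (se 0.13), 95% CI [6.649, 7.193]
#>   n = 12 points, R^2 = 0.9987
```

The estimate recovers the generating 7 µM within the bootstrap interval:
with 1% area noise a 12-point series pins K_D to a few percent.

Mutational free-energy bookkeeping from a table of variant dissociation
constants (mM, 5 °C) against the wild type:

```r
ddgTable(sfbglyMutantTable())[, c("name", "kd", "ddg")]
#>        name    kd       ddg
#> 1 wild-type 0.008  0.000000
#> 2     N112S 1.200 11.587290
#> 3     N157S 0.028  2.897063
#> 4     D166S 0.100  5.840846
#> 5     M210A 3.600 14.127874
#> 6     L214A 5.400 15.065528
#> 7     Y303A    NA        NA
```

Positive ΔΔG (kJ/mol) means the variant dimer dissociates more easily;
the three apolar-residue mutants cluster near 14 kJ/mol each, while the
hydrogen-bond-site mutants cost less. A variant observed only as a
monomer (Y303A) gets a lower bound instead of a number. The four
symmetry-related interface hydrogen bonds sum to
`hbondEnergyBudget(c(2.9, 6.6), c(2, 2))` = 19 kJ/mol.

Kinetics, with rates extracted from noisy product time courses:

```r
ds <- simulateTimecourse(kcat = 143, km = 1.1, E0 = 0.09,
                         substrateConcs = seq(0.1, 10, length.out = 10),
                         noiseCv = 0.02, seed = 11)
fitMichaelisMenten(ds)
#> Michaelis-Menten fit
#>   kcat = 143.1 +/- 2.1 min^-1
#>   Km   = 1.121 +/- 0.08 mM
#>   kcat/Km = 127.6 +/- 7.5 min^-1 mM^-1
```

See `vignettes/homodimer-dissociation.Rmd` for the model, assumptions
and numerical choices.

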