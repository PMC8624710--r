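# franzperm

Analysis of in vitro permeation tests (IVPT) run in Franz diffusion cells,
built for studies comparing transdermal delivery of an active drug and its
ion-pair prodrugs (here: ibuprofen paired with L-valine alkyl esters)
through excised human skin and the Strat-M synthetic membrane.

## What it computes

A Franz cell holds a donor formulation above a membrane and a stirred
receptor chamber below. At predefined times a sample of volume
`V_sample` is withdrawn from the receptor (volume `V_receptor`) and
replaced with fresh buffer; the assayed concentrations `c_n` (µg/mL) are
the pipeline's input. The stages:

1. **Dilution correction.** Cumulative amount permeated per membrane
   area: `Q_n = (c_n·V_receptor + V_sample·Σ_{i<n} c_i) / area` (µg/cm²).
2. **Steady-state kinetics.** Ordinary least squares of `Q` on `t` over
   the contiguous window (≥ 4 points, positive slope) that maximizes r²:
   the slope is the steady-state flux `J_ss` (µg·cm⁻²·h⁻¹), the x-axis
   intercept is the lag time `L_T` (h), and the permeability coefficient
   is `K_p = J_ss / C_donor` (cm/h).
3. **Membrane accumulation.** Drug deposited in the membrane from the
   end-of-study solvent extraction: `C_supernatant·V_extract/m_membrane`
   (µg/g), convertible between salt and active-moiety bases.
4. **Comparative statistics.** Per-membrane one-way ANOVA with Tukey HSD
   compact letter displays, inter-membrane flux ratios, Pearson
   correlation of mean profiles between membranes (per compound and
   pooled), and Ward (`ward.D2`) clustering of standardized mean profiles.
5. **Dose equivalence.** Ion-pair salts are weighed so every cream
   delivers the same active dose: `active = salt·M_active/M_pair`.

A mechanistic simulator provides ground truth for all of it: Fickian
diffusion through a homogeneous membrane (diffusivity `D`, thickness `h`,
partition coefficient `K`) under infinite dose and perfect sink, with

    Q(t) = K·h·C·[ D·t/h² − 1/6 − (2/π²) Σ ((−1)ⁿ/n²) exp(−D·n²π²·t/h²) ]

so `kp = K·D/h` and `L_T = h²/(6D)` exactly, plus the
withdrawal/replacement sampling protocol and multiplicative assay noise.

## Worked example

Simulate a triplicate 10-compound × 2-membrane study at 5% assay CV,
analyze it, and render the report:

```r
library(franzperm)
cfg <- study_config(noise_cv = 0.05, n_cells = 3, seed = 42)
out <- tempfile("demo_")
cmd_simulate(cfg, out_dir = out)
cmd_analyze(file.path(out, "concentrations.csv"), cfg,
            out_dir = file.path(out, "res"))
cmd_report(file.path(out, "res"))
```

The report starts:

```
Permeation parameters (mean over cells)
compound         membrane        Jss    Kp*10^3       LT  letters    ratio
[IBU]            skin          38.02       0.76     1.36       bc     4.21
[IBU]            strat-m      159.90       3.20     1.36        e     4.21
[ValOAm][IBU]    skin          54.68       1.09     1.18        e     2.96
...
Profile clusters (1 = fastest permeation)
  cluster 1: [ValOAm][IBU], [ValOBu][IBU], [ValOiPr][IBU], [ValOPr][IBU]
  cluster 2: [IBU], [ValOEt][IBU], [ValOMe][IBU]
  cluster 3: [ValOHept][IBU], [ValOHex][IBU], [ValOOct][IBU]
```

Reading it: the free acid permeates skin at `J_ss ≈ 38 µg·cm⁻²·h⁻¹`
(`K_p·10³ ≈ 0.76 cm/h` at `C_donor = 50,000 µg/cm³`), the Strat-M
membrane passes ~4.2× more flux for the same cream (`ratio`), compounds
sharing a Tukey letter within a membrane are statistically
indistinguishable at α = 0.05, and the propyl/isopropyl/butyl/amyl ester
pairs cluster together as the fastest-permeating group — recovering the
generator's ground-truth kinetics (the fitted `K_p·10³` values sit within
a few percent of the panel values the study was simulated from).

The same pipeline runs from the shell:

```sh
Rscript -e 'franzperm::franz_cli()' simulate --seed 42 --out runs/sim
Rscript -e 'franzperm::franz_cli()' analyze --dataset runs/sim/concentrations.csv --out runs/res
Rscript -e 'franzperm::franz_cli()' report --results runs/res
```

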