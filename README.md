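# oligoantigen

Tools for designing and evaluating **LNA/DNA oligonucleotide antigens** for
the detection of anti-DNA antibodies, the autoantibodies characteristic of
systemic lupus erythematosus (SLE). Clinical anti-dsDNA assays rely on
heterogeneous natural DNA antigens with poor reproducibility; synthetic
oligonucleotides carrying locked nucleic acid (LNA) monomers are
sequence-defined and thermally stabilised alternatives. This package is for
computational biologists and assay developers who want to design such
antigens and quantify their behaviour end to end.

The chain covers four stages, each a package module with seeded synthetic
generators standing in for clinical and simulation data:

1. **Sequence design** (`R/oligo_model.R`, `R/antigen_design.R`) — mixmer
   `+` notation, dinucleotide-repeat construction from the dTdC seed with
   the T→A / C→T mutation scheme, exhaustive self-dimer and hairpin screens,
   a GC% > 75 rejection filter, separated LNA placement (one middle, two
   near termini), and duplex melting temperature by nearest-neighbor
   thermodynamics plus an additive per-LNA increment (ΔTm/LNA ∈ [2, 8] °C,
   default +4).
2. **Interface metrics** (`R/structure_analysis.R`) — Shrake–Rupley
   solvent-accessible surface area; buried contact area
   S = S_protein + S_nucleic − S_complex; switched-cutoff nonbonded energy
   (Coulomb 332.0636·q₁q₂/r plus Lennard-Jones, C¹ switch from 10 to 12 Å);
   geometric hydrogen-bond and π-stacking detection with trajectory
   occupancies.
3. **SPR kinetics** (`R/spr_kinetics.R`) — the 1:1 Langmuir model
   dR/dt = kₐC(R_max − R) − k_d R in closed form, binding/stability report
   points, the two-fold dilution series, global Levenberg–Marquardt fitting
   of (kₐ, k_d, R_max) with K_D = k_d/kₐ derived exactly, plausibility
   flags and cut-off positivity calls.
4. **ELISA statistics** (`R/elisa_stats.R`) — per-sample dispersity over
   explicit antigen subsets, Welch t-test, one-way ANOVA, OLS assay
   comparison, and boxplot statistics with Q1 − 1.5·IQR / Q3 + 1.5·IQR
   arms.

The `analysis/` directory holds numbered drivers that run the stages in
order and write their tables under `results/`.

## Worked example

```r
library(oligoantigen)

s1 <- parse_lna_notation("TCC + TCT CTT TCT + CTT TCT + CTT", name = "SEQ1")
s1
#> <annotated_strand> SEQ1 (21 nt, 3 LNA, 5'->3')
#>   TCC +TCT CTT TCT +CTT TCT +CTT
base_composition(s1)$percent
#>  C  T
#> 38 62

tm <- estimate_tm(make_duplex(s1))
sprintf("Tm %.1f C (unmodified %.1f C), +%.1f C per LNA",
        tm$tm_celsius, tm$tm_unmodified_celsius, tm$delta_per_lna)
#> "Tm 67.0 C (unmodified 55.0 C), +4.0 C per LNA"

serial_dilution(2.5, 2, 5, 2)        # the antibody dilution series, mg/mL
#> [1] 2.50 1.25 0.63 0.31 0.16

sgs <- gen_sensorgram_set(list(ka = 1e5, kd = 1e-3, rmax = 400,
                               noise_sd = 4, seed = 1))
fit_kinetics(sgs)
#> 1:1 kinetic fit: ka = 1.005e+05 /(M s), kd = 0.001007 /s,
#>   KD = 1.002e-08 M, Rmax = 400.1 RU (SSE 1.912e+04)

plate <- gen_elisa_plate(list(n_samples = 30, seed = 2016))
dispersity_report(plate, c("LNA", "DNA"))$summary
#>   group      mean        sd  n
#> 1   LNA 0.6976265 0.2389544 30
#> 2   DNA 0.3551179 0.1934963 30
```

Reading the output: the parsed 21-mer carries three locked positions
{4, 13, 19} and the tabulated 62% T / 38% C content; its duplex is
predicted 12 °C more stable than the unmodified duplex (three LNAs at +4 °C
each); the global fit recovers the generating rate constants within a
fraction of a percent at 1% noise; and the LNA antigen group shows the
wider per-sample dispersity, the qualitative contrast the ELISA analysis
looks for.

The full narrative run is:

```sh
Rscript analysis/01_design_antigens.R
Rscript analysis/02_interface_metrics.R
Rscript analysis/03_spr_kinetics.R
Rscript analysis/04_elisa_stats.R
```

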