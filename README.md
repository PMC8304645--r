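# ifacedyn

Quantifying the stability of a protein–protein interface from molecular
simulation output.

`ifacedyn` was written for the kind of question asked about the human
microsomal triglyceride transfer protein (hMTP), a heterodimer of a large
α subunit and protein disulfide isomerase (PDI): does a small-molecule
ligand bound at the PDI b′ domain loosen the subunit interface? The package
implements the trajectory-analysis layer of that study design — it does not
run molecular dynamics. Its inputs are structures (PDB), multi-frame
coordinate trajectories (multi-model PDB or a plain frame-table text
format), and steered-pulling records (CSV); its outputs are tidy tibbles.

## What it computes

**Interface composition.** Two atoms, one per binding partner, are an
*interface atom pair* when their distance is ≤ 5 Å; two residues are an
*interface contact* when their Cα–Cα distance is ≤ 7 Å in at least one
analysed conformation. Counts and buried surface areas (Shrake–Rupley SASA
difference, probe 1.4 Å; a radical-plane contact-area method is available
as an alternative) are decomposed by the PDI-side domain (N-terminal, a, b,
b′, x, a′, C-terminal), with interface contacts grouped into regions
1/2/3/3′ keyed to the a, b′, a′ and C-terminal domains.

**Per-contact flexibility.** For contact *ij* over *N* frames, the
mean-square fluctuation of distance is the population variance of the
Cα–Cα distance:

    MSFD_ij = (1/N) Σ_k (R_ij,k − R̄_ij)²   [Å²]

High MSFD marks a flexible, unstable contact. Supporting rules: contacts of
the α-subunit's C-terminal tail (residues 886–894) are excluded when their
MSFD exceeds 14 Å² in any condition; two conditions are compared by
counting contacts whose MSFD differs by more than 1 Å² in either
direction; region averages pool member contacts.

**Binding strength.** From an ensemble of constant-velocity harmonic-trap
pulling replicas (trap stiffness k, velocity v), the work
W(t) = ∫ F·v dt is accumulated per replica and the potential of mean
force along the pulled distance λ = v·t is estimated by Jarzynski's
equality, exp(−βΔF) = ⟨exp(−βW)⟩, in its second-cumulant form

    ΔF(λ) ≈ ⟨W⟩ − β(⟨W²⟩ − ⟨W⟩²)/2,   β = 1/k_B T,

with the direct exponential average (log-sum-exp) always reported
alongside as a cross-check.

**Synthetic data with known answers.** Because production MD trajectories
for such systems are rarely deposited, a first-class generator module
produces (i) two-chain toy complexes with an exactly known ≤ 7 Å contact
set, (ii) trajectories whose designated contact distances fluctuate with
prescribed variance σ² (or A²/2 for a sinusoid), and (iii) overdamped
Brownian pulling ensembles in flat or harmonic wells, whose free-energy
change is 0 or κkλ²/(2(κ+k)) in closed form. Every downstream statistic
can therefore be checked against an exact or analytic target.

## Worked example

Two simulated "conditions" of one toy complex, the second with inflated
interface fluctuations, then a pulling ensemble with a known free-energy
curve:

```r
library(ifacedyn)

tc    <- make_toy_complex(n_a = 6, n_b = 6, contact_fraction = 0.5, seed = 1)
quiet <- make_fluctuation_trajectory(tc$structure, tc$contacts,
                                     n_frames = 400, sigma = 0.3, seed = 2)
loose <- make_fluctuation_trajectory(tc$structure, tc$contacts,
                                     n_frames = 400, sigma = 1.8, seed = 3)

report <- run_interface_analysis(
  list(apo = quiet$trajectory, holo = loose$trajectory),
  config = analysis_config())

report$contacts
#> <iface_contact_set> 12 contacts (source: multi-source-union)
#> # A tibble: 12 × 5
#>    chain_a resno_a chain_b resno_b region
#>    <chr>     <int> <chr>     <int> <chr>
#>  1 A           604 B           235 region2
#>  ...

report$comparisons
#> # A tibble: 1 × 4
#>   condition_a condition_b n_a_higher n_b_higher
#> 1 apo         holo                 0          9
```

The contact universe is the union over both trajectories' frames; all 12
contacts fall in region 2 because the toy PDI chain is numbered inside the
b′ domain. Nine contacts gained more than 1 Å² of MSFD in the `holo`
condition and none moved the other way — the injected loosening, read back
out.

```r
en  <- simulate_brownian_pull(pulling_protocol(v = 1, k = 10, duration = 2),
                              potential = "harmonic", kappa = 1,
                              gamma = 0.1, dt = 1e-4, n_replicas = 100,
                              seed = 4)
pmf <- pmf_curve(en)
glance(pmf)
#> # A tibble: 1 × 5
#>   lambda_max_A dF_final mean_W_final n_replicas temperature
#> 1            2     1.76         1.95        100         300
en$ground_truth(2)
#> [1] 1.818182
```

At λ = 2 Å the cumulant estimate (1.76 kcal/mol) sits within a few percent
of the closed-form composite-harmonic value 20/11 ≈ 1.82 kcal/mol, and
below the mean work, as the second law requires. `autoplot(pmf)`,
`plot_msfd()` and `plot_force_distance()` give the standard figures.

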