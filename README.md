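# coorient

Quantifying the **co-orientation** of two biological constructs — how
consistently one set of axial directions is oriented relative to another,
beyond what either set's own organization implies.

## The problem

Fluorescence micrographs of tissue routinely yield per-pixel orientations
for several constructs at once: actin fibrils and sarcomeric Z-lines in
cardiomyocytes, collagen and cells in valves, matrix fibrils and the cells
on them. These orientations are *axial* data — a direction without a sense,
so θ and θ + π are the same measurement. Classical tools summarize one
construct at a time: the orientational order parameter (OOP) of a set of
pseudo-vectors `k_i = (cos θ_i, sin θ_i)` is the maximum eigenvalue of the
mean order tensor

    T = 2 ⟨ k kᵀ ⟩ − I,

which runs from 0 (isotropic) to 1 (perfectly aligned), with the
corresponding eigenvector (the *director*) giving the mean orientation.
But the OOP says nothing about whether two constructs are oriented
consistently *with respect to each other*.

`coorient` implements the co-orientational order parameter (COOP): for
index-paired constructs P and Q, form the relative-angle field

    f_i = ( p_i · q_i , | p_i × q_i | ) = ( cos(β_i − α_i), sin(β_i − α_i) ),

and take the OOP-style eigenvalue of *its* mean order tensor. The COOP is
1 when the two constructs hold a fixed relative angle everywhere, 0 when
their relative angle is maximally disordered, and it is invariant to global
rotation of either field, to the θ ↔ θ + π pseudo-vector ambiguity, and to
swapping P and Q. The director of the relative-angle tensor encodes the
mean inter-construct angle θ₀ (e.g. ~90° for Z-lines vs actin in healthy
sarcomeres).

Two analytic reference points position a measured COOP:

* **Uncorrelated bound** `COOP_u = OOP_P · OOP_Q` — the value reached by
  statistically independent constructs;
* **Correlated bound** `COOP_c = min(OOP) / max(OOP)` — the value reached
  when one construct is the other plus independent random noise;
* **Normalized COOP** `(COOP − COOP_u) / (COOP_c − COOP_u)` — < 0
  anti-correlated, 0 uncorrelated, 1 correlated, > 1 ultra-correlated.

The package also provides the associated power analysis (delta-method error
propagation of both bounds plus a Welch t-test: maximum tolerable OOP error
and minimum sample size), seeded synthetic generators for every validation
regime (including the exact anti- and ultra-correlated constructions), and
the image-scale pipeline: grid partitioning, per-square directors, the
weight `W_i = OOP_P,i · OOP_Q,i · ρ_P,i · ρ_Q,i`, weighted COOP, pairwise
consistency matrices across samples, and period-aware multi-sample mean
angles.

## Worked example

A noise-coupled pair: construct P is a truncated-Gaussian field
(σ = 0.25 rad), construct Q is P plus calibrated noise targeting
OOP_Q ≈ 0.55:

```r
library(coorient)
pf  <- gen_correlated_pair(n = 20000, sigma_p = 0.25, target_oop_q = 0.55, seed = 42)
res <- coop(pf)
res
#> <coop_result>  n = 20000
#>   COOP = 0.6163   (COOP_u = 0.4799, COOP_c = 0.6187)
#>   OOP_P = 0.8807, OOP_Q = 0.5449
#>   theta0 = 0.0020 rad (0.1 deg)
#>   normalized COOP = 0.9830, regime: normal
```

The measured COOP sits essentially on the correlated bound
(normalized COOP ≈ 1), exactly what a construct-plus-random-noise coupling
should produce, and the mean inter-construct angle is ~0 because the noise
is centered. Experiment planning uses the same bounds:

```r
round(max_tolerable_error(0.6, 0.6, n = 4), 3)   # largest usable OOP error at N = 4
#> 0.18
min_sample_size(0.6, 0.6, sigma_oop = 0.04)      # samples needed at sigma_OOP = 0.04
#> 2
```

A command-line front end (`exec/coorient`) exposes the same operations as
subcommands (`oop`, `coop`, `bounds`, `normalize`, `simulate`, `grid`,
`consistency`, `power`) over CSV/TSV angle files; every run writes a
`manifest.json` with its parameters and seed.

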