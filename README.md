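# oligopb

Membrane proteins often function as monomers, dimers, or higher-order
oligomers, and which state dominates is a biological question in its own
right. Single-molecule pulldown of GFP-tagged complexes in polymer lipid
nanodiscs answers it by photobleaching: each captured complex is imaged by
TIRF microscopy until its fluorophores bleach, and the number of discrete
intensity drops counts the mature GFP copies it carried. `oligopb` is the
computational side of that experiment, for microscopists and biophysicists
who have intensity traces (or step tallies) and want a defensible
monomer/dimer/oligomer distribution out the other end.

The raw step distribution is *not* that distribution. GFP matures with
probability r ≈ 0.7, so a dimer carries a single mature copy with
probability 2r(1−r) and masquerades as a monomer; complexes with no mature
copies are never seen at all. `oligopb` models both effects explicitly.
With π<sub>s→w</sub> = C(s,w) r<sup>w</sup>(1−r)<sup>s−w</sup> the
maturation probabilities and

&nbsp;&nbsp;&nbsp;&nbsp;η<sub>s→0</sub> = 0, &nbsp;
η<sub>s→w</sub> = π<sub>s→w</sub> / (1 − π<sub>s→0</sub>) for w ≥ 1,

the observed step count of trace n follows
w<sub>n</sub> | s<sub>n</sub> ~ Categorical(η<sub>s<sub>n</sub>→·</sub>),
with prior s<sub>n</sub> | q ~ Categorical(q₁, q₂, q₃) and
q ~ Dirichlet(1, 1, 1). The posterior of q — the corrected oligomer
distribution — is sampled by a two-block Gibbs sampler with exact
conditionals, validated against the conjugate closed form (r = 1) and an
independent simplex-quadrature oracle.

The package also provides the upstream and supporting steps:

* a deterministic, scale-equivariant photobleaching **step detector**
  (penalized least-squares change-point segmentation with auditable
  rejection rules) and the monomer/dimer/≥3 binning;
* a **simulator** for step counts and full intensity traces with ground
  truth, in a model-faithful mode and a physical-maturation mode;
* **co-capture statistics** (expected occupancy λ = ρπ(d/2)² and the
  conditional Poisson probability of two receptors sharing a disc),
  **GPMV surface-density calibration**, and **internal-standard lipid
  quantitation**;
* a command-line interface (`simulate`, `detect`, `infer`, `cocapture`,
  `gpmv-density`, `lipid-quant`, `report`) plus CSV/TSV/JSON and a legacy
  binary trace dialect.

## Worked example

Simulate a pure-dimer population seen through 70% maturation, then correct
it:

```r
library(oligopb)

sim <- simulate_counts(c(0, 1, 0), r = 0.7, n_traces = 2000, seed = 11)
sim$counts
#> Photobleaching step counts (w = 1, 2, >=3):
#>   n1 = 936, n2 = 1064, n3 = 0  (N = 2000)

fit <- oligo_fit(sim$counts, r = 0.7, seed = 12)
summary(fit)
#> Oligomer distribution corrected for GFP maturation
#>   counts: n1 = 936, n2 = 1064, n3 = 0  (N = 2000);  r = 0.7
#>   posterior mean (SD):
#>     monomer   0.023 (0.015)
#>     dimer     0.976 (0.015)
#>     oligomer  0.001 (0.001)
#>   95% credible intervals:
#>     monomer   [0.001, 0.056]   ESS 234
#>     dimer     [0.943, 0.998]   ESS 298
#>     oligomer  [0.000, 0.005]   ESS 3328
#>   posterior-predictive step fractions (predicted / empirical):
#>     w=1  0.473 / 0.468
#>     w=2  0.526 / 0.532
#>     w=3  0.001 / 0.000
#>   max predictive discrepancy: 0.006
```

Although 47% of the traces show a single step, the corrected posterior
puts 97.6 ± 1.5% of the population in the dimer class: the maturation
model attributes the one-step traces to dimers with one dark copy. The
posterior-predictive fractions match the empirical ones, confirming the
fit. `plot(fit)` draws the raw-vs-corrected bar chart; `coef()`,
`confint()`, `residuals()` and `simulate()` behave as for any fitted
model.

Is an apparent dimer ever just two monomers sharing a disc? At the
experimental operating point (253 molecules/µm², 25 nm discs):

```r
cocapture_probability(253, 25)
#> $lambda
#> [1] 0.1241911
#> $p_cocapture
#> [1] 0.06081059
```

so an occupied disc holds a second, unrelated receptor only ~6% of the
time.

From the shell, the same pipeline end to end:

```sh
oligopb simulate --q 0.2,0.3,0.5 --r 0.7 --n 2000 --seed 7 --traces --out-dir run/
oligopb detect   --traces run/traces.csv --out run/steps.tsv
oligopb infer    --steps run/steps.tsv --r 0.7 --seed 1 --out run/posterior.json
```

(the `oligopb` script is installed under
`system.file("cli", "oligopb", package = "oligopb")`).

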