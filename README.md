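# mdensemble

Comparative analysis of molecular dynamics conformational ensembles in R.

`mdensemble` implements, as one coherent and tested toolbox, the analyses a
structural-biology group runs when contrasting two simulated states of a
protein complex — for example a calcium-bound versus calcium-free
calmodulin–kinase assembly:

* **Superposition & RMSD** — Kabsch least-squares fitting (SVD, reflection
  excluded) and RMSD time series against a crystal reference, pooled over
  replicas.
* **Essential dynamics** — diagonalization of the 3N × 3N Cα covariance
  matrix, projection onto PC1/PC2, and a Boltzmann-inverted free-energy
  landscape ΔG = −k<sub>B</sub>T ln(ρ/ρ<sub>max</sub>) with
  persistence-based basin detection.
* **Dynamical cross-correlation** — C<sub>ij</sub> = c<sub>ij</sub> /
  (c<sub>ii</sub> c<sub>jj</sub>)<sup>1/2</sup> over displacement vectors,
  display masking of |C| < 0.4, and inter-domain summaries.
* **Dynamic network analysis** — a residue contact graph (any heavy-atom
  pair within 4.5 Å in more than 75% of frames), edge distances
  D<sub>ij</sub> = −ln|C<sub>ij</sub>|, Girvan–Newman community
  decomposition at maximum modularity (communities of fewer than three
  residues pruned), and difference contact network analysis between two
  states.
* **Ion solvation** — radial pair distribution functions g(r) with the
  running coordination integral n(r) = ρ∫4πs²g(s)ds, plus per-site
  coordination-mode catalogues (sidechain/backbone/water oxygens).
* **Ensemble clustering** — pairwise-RMSD GROMOS-style clustering,
  medoid representative structures, cross-state RMSD.
* **MM–GBSA energetics** — single-trajectory interaction-energy
  decomposition: Coulomb and 12-6 Lennard-Jones cross terms, a
  pairwise-descreening generalized-Born polar term, and the nonpolar
  surface-area model ΔG<sub>nonpolar</sub> = γ·ΔSASA + b
  (γ = 0.0072 kcal mol⁻¹ Å⁻², b = 0) with Shrake–Rupley surface areas;
  per-term ΔΔG between states.

Because microsecond trajectories cannot ship with a package, a first-class
**synthetic-ensemble module** generates the inputs with known ground truth:
Gaussian fluctuation ensembles with a prescribed residue–residue
correlation matrix, two-substate conformational mixtures with true labels,
and ion/solvation-shell toy systems whose g(r) is analytic. Every analysis
stage is validated against these constructions and against independent
oracles (quaternion superposition, brute-force summation, exhaustive
maximum-modularity enumeration, fine-quadrature surface areas).

## Worked example

Generate a two-block ensemble whose blocks are internally correlated
(C = 0.7) and mutually anti-correlated (C = −0.5), then recover that
structure with the cross-correlation machinery:

```r
library(mdensemble)

N <- 24; blk <- 12
C <- matrix(-0.5, N, N)
C[1:blk, 1:blk] <- 0.7; C[(blk + 1):N, (blk + 1):N] <- 0.7
diag(C) <- 1

set.seed(42)
ref  <- matrix(rnorm(3 * N, sd = 8), N, 3)
spec <- ensemble_spec(ref, C, amplitudes = 0.3, n_frames = 5000, seed = 42)
traj <- generate_correlated_ensemble(spec)
traj
#> md_trajectory: 5000 frames x 24 atoms

cm <- dccm(traj, 1:N, reference = NULL)
cm
#> correlation_matrix: 24 x 24 ; range [-0.507, 1.000]

s <- interdomain_summary(cm, 1:blk, (blk + 1):N)
sprintf("inter-domain mean C = %.3f, fraction anti-correlated = %.2f",
        s$mean, s$fraction_anti)
#> "inter-domain mean C = -0.498, fraction anti-correlated = 1.00"
```

The recovered inter-block mean (−0.498) matches the prescribed −0.5 to
Monte-Carlo accuracy; the fraction of residue pairs below the −0.4
anti-correlation cutoff is 1, as built. A coordination scan of the bundled
idealized EF-hand calcium site (synthetic geometry carrying the canonical
ligand identities of calmodulin's second N-lobe site) shows the textbook
pentagonal-bipyramidal sevenfold shell:

```r
coordination_mode(synthetic_calcium_site(), ion = 1L, cutoff = 3.0)
#> coordination_shell: CN = 7 within 3 A of CAL 500
#>   resid resno chain elety    category distance
#> 1   ASP    56     B   OD1 sidechain O      2.4
#> 2   ASP    58     B   OD1 sidechain O      2.4
#> 3   ASN    60     B   OD1 sidechain O      2.4
#> 4   THR    62     B     O  backbone O      2.4
#> 5   ASP    64     B   OD1 sidechain O      2.4
#> 6   GLU    67     B   OE2 sidechain O      2.4
#> 7   GLU    67     B   OE1 sidechain O      2.4
```

The whole two-state comparison runs from one configuration:

```r
report <- run_pipeline(list(seed = 1))      # writes mdensemble-report/
report$results$dccm$unbound$interdomain_mean   # more anti-correlated ...
report$results$gbsa$ddG                        # ... and weaker binding
```

or from the shell via the thin CLI at `inst/cli/mdensemble`
(`fit-rmsd`, `pca-fel`, `dccm`, `network`, `dcna`, `solvation`, `cluster`,
`gbsa`, `run-all`, `synth` subcommands).

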