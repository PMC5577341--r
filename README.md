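# remscape

Conformational-landscape analysis for replica-exchange (REMD) ensembles of
intrinsically disordered peptides, built around the amyloid-beta 42-mer
(Aβ42) and its N-terminal hexapeptide ligands (Aβ6: wild type `DAEFRH` and
the A2V/A2T variants). The package is for structural-bioinformatics users
who have (or simulate) multi-replica peptide trajectories and want the
standard monomer-ensemble readouts as tidy tables:

* **Secondary structure** — hydrogen-bond (Kabsch–Sander) assignment into
  five classes (α, 3₁₀, strand, turn, coil), per-residue propensity
  profiles and bound-minus-free difference profiles with block standard
  errors.
* **Tertiary/quaternary structure** — Cα and heavy-atom contact-probability
  maps, thresholded difference maps, per-residue interchain contact counts,
  D23–K28 salt-bridge frequency, radius of gyration, backbone-RMSD
  convergence series, Shrake–Rupley (hydrophobic) SASA.
* **Free-energy landscape** — the two reaction coordinates
  Nβ(CHC+CTR) (normalized strand count over residues 17–21 ∪ 30–42) and
  NC(CHC–CTR) (normalized Cα contact count between the two regions); the
  2D potential of mean force W = −k_B T ln(P/P_max); populations of
  rectangular states S1–S6 (+ Others) with block errors; the
  Nβ > 0.6 hairpin filter.
* **Clustering** — gromos-style greedy max-neighbour clustering under a
  pairwise Cα-RMSD cutoff (0.3 nm default), with cumulative top-k
  populations.
* **Binding energetics** — single-trajectory MM-GB/SA decomposition:
  interchain Coulomb + Lennard-Jones, generalized-Born polar solvation
  (HCT radii, Still f_GB), SASA nonpolar term; ΔG_bind = ΔE_vdW + ΔE_elec +
  ΔG_polar + ΔG_nonpolar, each mean ± block SE.
* **Synthetic data** — a toy REMD sampler (geometric temperature ladder,
  Metropolis exchanges) and a state-mixture generator with planted
  populations, planted per-residue structure and a planted salt-bridge
  frequency, used to validate the whole pipeline end to end.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` ggplots; ensembles and topologies are light S3 containers in
the `bio3d` tradition.

## Worked example

Generate a free-monomer-like synthetic ensemble with a planted 47%
hairpin-rich state and a 13% D23–K28 salt bridge, then recover both:

```r
library(remscape)

spec <- state_mixture_spec(list(
  mixture_state("S6",   0.47, hairpin_p = 1, salt_bridge_p = 0.13),
  mixture_state("open", 0.53, helix_regions = 3:10, salt_bridge_p = 0.13)
), n_frames = 800, seed = 42)

mix    <- sample_mixture_ensemble(spec)
labels <- assign_ss_ensemble(mix$ensemble)
rc     <- rc_series(mix$ensemble, labels = labels)

state_populations(rc, n_blocks = 4)
#> # A tibble: 7 x 3
#>   state  mean_pct se_pct
#> 1 S1       54.2    2.55
#> 2 S2        0      0
#> 3 S3        0.875  0.427
#> 4 S4        0.125  0.125
#> 5 S5        0      0
#> 6 S6       44.8    2.95
#> 7 Others    0      0

salt_bridge_frequency(mix$ensemble, 23, 28)
#> # A tibble: 1 x 3
#>   frequency_pct se_pct n_frames
#> 1          14.1   1.09      800
```

The S6 rectangle (high Nβ, high NC — the CHC–CTR β-hairpin corner)
recovers the planted 44.75% of hairpin frames exactly, within one block SE
of the 47% target fraction; the salt-bridge estimate recovers its planted
draw likewise. `pmf2d(rc)` turns the same series into the free-energy
surface (`autoplot(pmf2d(rc), states = default_state_rectangles())`), and
`hairpin_subset(mix$ensemble, rc)` isolates the frames a gromos clustering
(`gromos_cluster(pairwise_rmsd_matrix(...), 0.3)`) decomposes into
conformational families.

`run_pipeline(pipeline_config(seed = 1))` chains every stage for a
free-vs-bound pair and writes the tables (`fig2_ss_profile_*.csv`,
`fig3_contact_diff.csv`, `table1_state_populations_*.csv`,
`fig4a_energetics.csv`, `fig5_pmf_free.csv`, ...) plus a manifest into the
configured output directory.

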