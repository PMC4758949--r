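# supprox

Residue proximity from saturation-suppressor mutagenesis, and structural
model discrimination built on it.

## The problem

When a destabilising substitution at a buried residue (a *parent inactive
mutant*, PIM) is rescued by a second-site *suppressor*, the two residues
are often in physical contact. An exhaustive suppressor screen therefore
yields residue–residue proximity constraints without solving a structure —
provided one can tell *proximal* suppressors (direct contact partners)
from *distal/global* ones (surface mutations that stabilise the whole
protein). `supprox` implements the computational side of that workflow
for deep-mutational-scanning data:

* **MS_seq** — per-mutant mutational sensitivity from read counts across
  expression levels (MIDs): the first MID at which a mutant's reads drop
  fivefold or more relative to the previous MID (2 = most active, 9 =
  never active, 0 = mutant absent from the library).
* **RankScore** — per-position mean of population-percentile ranks of its
  mutants' MS_seq values (rank(2) = 1; rank(k) = cumulative % of mutants
  with MS_seq < k, + 1). At non-active-site positions it is a proxy for
  residue burial: suppressors with RankScore ≤ 1 are called distal,
  ≥ 25 proximal.
* **ContactScore** — for a candidate structural model *m* and *n*
  experimentally derived contact pairs,
  `CSc(m) = Σᵢ S(xᵢ, yᵢ)` with `S(x, y) = 1` if the side-chain centroids
  of x and y are < 7 Å apart in *m*; an integer in 0..n used to recover
  native-like models from a decoy set.
* **rdepthscore** — Pearson correlation of RankScore with model-derived
  residue depth (distance to the nearest bulk-solvent surface point),
  higher in native-like models.
* **R_s** — packing deviation `Σᵢ |ASA_xi − ⟨ASA_x⟩| / ⟨ASA_x⟩` of
  per-residue accessible surface areas from reference means.
* **Differential contacts** — for two rival structures of one protein
  (e.g. an X-ray/NMR disagreement), positions whose inter-helical
  contact partners differ between the structures are selected by five
  criteria (not charged; no side-chain hydrogen bond to the partner;
  ≥ 2 partners in one structure; sequence separation > 30; partner sets
  shifted by > 6 positions) and suppressor pairs then arbitrate which
  structure is the functional conformer in vivo.
* **Melt fitting** — thermal-shift curves are fitted to the
  four-parameter sigmoid `y = LL + (UL − LL)/(1 + e^((Tm−T)/a))` to
  report melting temperatures of PIM/suppressor variants.

Geometry support (PDB I/O, side-chain centroids, Kabsch superposition and
backbone RMSD, per-residue RMSF over NMR ensembles, Shrake–Rupley solvent
accessibility, residue depth) and seeded synthetic-data generators for
every input are part of the package, so the whole pipeline is testable
end to end without downloads.

## Worked example

```r
library(supprox)

# six suppressor-derived contact constraints (CcdB screen layout)
pairs <- contact_pairs(read_table_schema(
  system.file("extdata", "ccdb_suppressor_pairs.tsv", package = "supprox"),
  "pairs"))
#> contact_pairs: 6 pair(s), cutoff 7 A

# synthetic native + decoys of known RMSD; recovery of full-constraint
# models per 0.5 A RMSD bin
bun <- generate_helix_bundle(seed = 1)
dec <- generate_decoys(bun$model, n_models = 60,
                       amplitudes = c(0.5, 1, 2, 4, 8), seed = 2)
# planted: the native's six tightest long-range side-chain contacts,
# standing in for an experimentally derived pair set (analysis/01 builds
# the same constraint table)
sc  <- score_decoys(dec$models, bun$model, planted)
recovery_histogram(sc, function(s) s$contact_score == 6)
#>   bin_lower bin_upper models_total models_selected  recovery
#> 1       0.0       0.5           12              12 1.0000000
#> 2       0.5       1.0           12              12 1.0000000
#> 4       1.5       2.0           12              11 0.9166667
#> 7       3.0       3.5            2               0 0.0000000
```

Low-RMSD decoys keep all six contacts (recovery 1.0); past ~3 Å none do
— that separation is what makes ContactScore a model discriminator.

```r
# rival-conformation arbitration on a domain-swap toy
tp  <- generate_toy_conformation_pair(seed = 1)
evaluate_suppressor_support(tp$planted[1:3, ], tp$A, tp$B)
#>   pim_pos sup_pos   dist_A    dist_B    verdict
#> 1       2      35 5.752038  8.185029 supports_A
#> 2      29      35 2.851802 11.944964 supports_A
#> 3      25      39 3.857093 11.280429 supports_A
#> summary: supports_A=3

# melting temperature from a noisy thermal-shift trace
fit_melt_curve(simulate_melt(LL = 0, UL = 1, a = 2, Tm = 55,
                             noise_sd = 0.02, seed = 3))
#> melt_fit: Tm = 54.92 C, a = 1.966 C, LL = -0.00137, UL = 0.998, |r| = 0.208
```

Every suppressor pair is close (≤ 7 Å) only in conformer A, so the
verdicts point at A as the generating structure; the melt fit recovers
the planted Tm of 55 °C to within 0.1 °C at 2 % noise.

The `analysis/` directory holds the same workflow as numbered drivers
(`Rscript analysis/01_synthetic_inputs.R [seed]`, then 02–05), each
writing its tables under `results/`.

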