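---
title: "Suppressor-derived contacts and structural model discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressor-derived contacts and structural model discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supprox)
```

This vignette is the package's account of its methods: the models and
scores it implements, the parameters that matter, the readings chosen
where a definition was genuinely open, what the synthetic-data
generators emulate (and what they do not), and the numerical choices
behind the implementation.

## From a suppressor screen to spatial constraints

A saturation-suppressor screen starts from a *parent inactive mutant*
(PIM): a destabilising substitution at a buried, non-active-site
residue. A second-site library in that background is screened for
*suppressors* — substitutions restoring activity. A proximal suppressor
typically restores packing by direct contact with the PIM (a cavity made
by a large-to-small substitution filled by a small-to-large partner);
a distal (global) suppressor is usually a surface mutation stabilising
the whole fold. Each (PIM, proximal suppressor) pair is therefore a
residue-proximity constraint, and a handful of such constraints is
enough to pick native-like models out of a large decoy set.

The package implements everything downstream of sequencing: scoring
mutants, aggregating to positions, separating proximal from distal
suppressors, turning pairs into model scores, and arbitrating between
rival structures.

## MS_seq: mutational sensitivity from read counts

The screen grows the library at increasing expression levels, each
tagged with a barcode (MID, used here directly as the expression-level
index, 2–9). Active (toxic) mutants kill their host at the expression
level where enough protein accumulates, so a mutant's read count
collapses at that MID. `ms_seq_from_reads()` scans MIDs in ascending
order and assigns MS_seq as the first level at which
`reads[previous] / reads[current] >= drop_factor` (default 5).
Conventions, fixed here and used by the generator as well:

* a drop from positive reads to zero qualifies (complete killing is the
  strongest signal); zero to zero does not;
* all-zero rows get the sentinel 0 (mutant absent from the library);
* mutants that never drop get 9: they survive every expression level,
  i.e. are never active, the least-active end of the scale;
* the drop is a *ratio to the previous MID*, so the lowest level (2) is
  only callable against a pre-selection baseline. The read-count schema
  therefore accepts an optional `mid_1` column (the unselected library);
  `simulate_reads()` emits it. Without `mid_1`, observable values start
  at 3 — a property of the scoring rule, not of the implementation.
* no interpolation is performed for mutants missing at intermediate
  MIDs; the scan uses the counts as given.

## RankScore and the proximal/distal cutoffs

Per position, MS_seq values are aggregated by population-percentile
ranks: mutants of stratum MS_seq = 2 get rank 1; mutants of stratum k
get rank (cumulative percentage of mutants with MS_seq < k) + 1.
RankScore is the mean rank of a position's observed mutants (MS_seq = 0
rows and wild-type self-substitutions are excluded). Two deliberate
choices:

* cumulative percentages enter the arithmetic **unrounded** — rounding
  percentages would make ranks depend on the whole-table composition in
  a discontinuous way and break order-invariance;
* no clipping to 100: the stratum arithmetic can reach
  (100 − a) + 1 for the top stratum, marginally above 100 when the
  bottom stratum is small. The observed range is documented rather than
  clipped, so the score stays an exact function of the distribution.

RankScore at non-active-site positions tracks residue burial: deeply
buried positions tolerate few substitutions, surface positions tolerate
nearly all. `classify_suppressor()` calls a suppressor position distal
when RankScore ≤ 1 (the conservative floor of the scale: such positions
are invariably exposed) and proximal when RankScore ≥ 25, a cutoff that
in practice selects only buried residues; in between the call is
"ambiguous" rather than forced. Both cutoffs are exposed parameters.

Active-site positions violate the burial relation — they are exposed
but highly sensitive, with a distinctive pattern: aliphatic
substitutions are poorly tolerated too. `classify_position()` encodes
the three motifs as rules over substitution classes — (G,P); aliphatic
A,C,V,L,I,M; aromatic H,F,Y,W; polar S,T,N,Q; charged D,E,K,R — with
two tunable thresholds: `high_ms = 7` (an MS_seq at or above which a
substitution counts as poorly tolerated) and `tol_fraction = 0.5` (the
fraction of a class required to express a motif). The motifs are
qualitative in origin; the defaults are the package's own calibration
and are configurable.

## ContactScore

For a model *m* and *n* constraint pairs, ContactScore is the number of
pairs whose **side-chain centroids** are within the cutoff in *m*. The
centroid is the unweighted mean of the heavy side-chain atoms (all heavy
atoms except N, CA, C, O and OXT); glycine, which has none, uses its CA
so the score is defined at every position. Side-chain centroids rather
than CA positions because suppressor side chains face their partner —
the centroids of a true pair are closer than their CAs.

The cutoff is strict (`< 7` Å) and parametric, so cutoff sweeps are one
call away. For homo-oligomers, a pair's distance is the minimum over all
chain pairings (within-protomer and across-protomer): suppressor screens
cannot tell which protomer the contact lives in, and real pairs do cross
dimer interfaces. `score_decoys()` adds a backbone RMSD (N, CA, C; the
minimal standard backbone set) to the reference after Kabsch
superposition, and `recovery_histogram()` reports, per RMSD bin, the
fraction of models a predicate selects. Bins are half-open (lower,
upper], width 0.5 Å, labelled by their upper edge; empty bins carry an
undefined (NA) recovery rather than a zero. The native-like RMSD
threshold defaults to 4 Å in the reported counts, with the stricter
2.5 Å reading available by filtering the score table.

## rdepthscore and residue depth

rdepthscore is the correlation (Pearson by default, Spearman by flag)
between per-position RankScore and per-residue depth computed from a
candidate model. Active-site positions are excluded via a user-supplied
list, because their sensitivity tracks function, not burial.

Residue depth here is the distance to the nearest bulk-solvent position,
computed without placing explicit waters: the solvent surface is
approximated by the probe-inflated Shrake–Rupley sphere points (atom
radius + 1.4 Å) of atoms with nonzero accessibility — i.e. the centres
of the closest possible water molecules — and an atom's depth is its
distance to the nearest such point. This is deterministic and
dependency-free; it is validated by ordering and correlation properties
(buried deeper than exposed, anti-correlation with accessibility), not
by agreement with any particular water-placement implementation.
Per-residue aggregation is the mean over heavy atoms by default, with
min exposed as an option, since either aggregation is defensible and
published depth tables do not always state theirs.

## Solvent accessibility and R_s

`sasa()` is a Shrake–Rupley implementation: deterministic quasi-uniform
sphere points (a golden-spiral construction, so results are
bit-reproducible at fixed `n_points`), Bondi van der Waals radii by
element, probe 1.4 Å, default 960 points per atom (per-residue areas
move by under 2 % on doubling; 120–240 points are adequate for scoring
many decoys and are used in the bulk analyses). Relative accessibility
divides by the theoretical maximum per residue type (Tien et al. 2013
reference values, shipped as constants); values slightly above 100 % are
possible for extended termini and are not clipped.

R_s sums `|ASA_i − ⟨ASA_type⟩| / ⟨ASA_type⟩` over the chain — a
packing-deviation score in which the native should rank low. The
reference means ⟨ASA_x⟩ must come from a structure set;
`mean_asa_reference()` computes them from any list of models, and the
analyses here derive them from the synthetic globule itself (a synthetic
calibration, labelled as such). No pretend "large-dataset" table is
shipped: users with a curated set of high-resolution structures should
build their reference from it.

## Differential contacts between rival structures

When two experimental structures of one protein disagree (the motivating
case: a crystal structure and a domain-swapped NMR ensemble of a
trimeric membrane kinase), suppressor pairs can arbitrate.
`contact_map()` lists all position pairs with minimum side-chain
centroid distance ≤ 7 Å (inclusive here, following the contact
definition used for map comparison), optionally restricted to
inter-helical pairs (both residues inside helix segments from the PDB
header, pairs within one helix instance removed) and with a mobile
region excluded (for the NMR ensemble: residues whose CA RMSF across
poses is high — the N-terminal third — are not trusted for contacts).
NMR ensembles default to pose 1; a min-over-poses mode reports the
closest distance across all poses.

`select_pim_candidates()` screens positions contacting in both maps but
with different partners, applying five criteria in order: (i) charged
positions removed (their substitutions confound stability with
electrostatics); (ii) positions side-chain hydrogen-bonded to a partner
removed — read here as a side-chain N/O donor–acceptor heavy-atom
distance ≤ 3.5 Å with no angular term, the standard distance-only
criterion, chosen because it is deterministic and parameter-free;
(iii) ≥ 2 partners in at least one structure; (iv) sequence separation
|X − Y| > 30, applied per structure to that structure's partners;
(v) partner divergence: the minimum over cross-structure partner
combinations of |y_B − y_A| must exceed 6. Criterion (v) is stated
tersely in the field ("partner difference > 6") and admits per-partner
and set-level readings; the set-level reading is used because the point
of the screen is that the two structures put X against genuinely
different neighbourhoods, which a single coincident partner pair would
already falsify.

`evaluate_suppressor_support()` then classifies each experimental
(PIM, suppressor) pair by comparing its minimum centroid distance to the
cutoff in each structure: `supports_A`, `supports_B`, `both` or
`neither`, with per-pair failures isolated so one unresolvable position
cannot sink the run.

## Melt-curve fitting

Thermal-shift traces are fitted to
`y = LL + (UL − LL) / (1 + exp((Tm − T)/a))` by Levenberg–Marquardt
least squares (`minpack.lm`). The exponent is parsed as `(Tm − T)/a` —
the only reading that gives a sigmoid rising to the unfolded plateau UL
as T grows, which is what a dye-binding unfolding signal does.
Initialisation is from the data: plateaus from the signal extremes, Tm
from the steepest slope of a lightly smoothed trace, and the slope
parameter from the sigmoid's midpoint-slope identity
a ≈ (UL − LL) / (4 max|dy/dT|), with one fallback start; flat traces are
rejected as "no transition" rather than fitted. A mirrored solution
(negative a) is renormalised so UL > LL always holds on output.
Temperatures are °C throughout.

## What the synthetic generators emulate

All pipeline inputs can be generated, seeded, with ground truth returned
alongside, so each stage has a closed-loop recovery test without any
download:

* **Helix-bundle natives** (`generate_helix_bundle()`): ideal
  α-helices (2.3 Å radius, 1.5 Å rise, 100°/residue) with backbone
  N/CA/C/O and a two-atom radial pseudo side chain. The *ring* layout
  places helices on a circle; permuting slot assignments rearranges
  packing interfaces. The *packed* layout (one central helix plus a
  ring at 7.6 Å axis spacing) is deliberately tight — two-atom side
  chains fill less space than real ones — and yields a realistic burial
  gradient: residue depths of about 3–8 Å and strong depth/accessibility
  anti-correlation. Residue identities follow burial (inward faces
  hydrophobic), with all 20 types guaranteed so reference-ASA tables can
  be built from the model.
* **Decoys** (`generate_decoys()`): native plus window-correlated
  Gaussian displacement per residue, rescaled to a target amplitude;
  RMSD is computed, not assumed. Displacements are Cartesian, so
  covalent geometry distorts — acceptable because no score here consumes
  bond geometry; in exchange, the generator covers any RMSD range
  deterministically without a folding engine.
* **Rival conformations** (`generate_toy_conformation_pair()`): the same
  chain built with two helices exchanged between packing slots (3 and
  n), so a helix face contacts a sequence-distant region in A and a
  different one in B — a domain-swap analogue. The planted differential
  pairs are verified at generation time (≤ 6.5 Å in A, > 8 Å in B, so
  strictly on either side of the 7 Å cutoff).
* **Reads** (`simulate_reads()`): flat counts at the coverage depth,
  dropping tenfold from the planted MS_seq MID on (safely past the
  fivefold rule), with optional negative-binomial overdispersion
  (variance = μ + 0.05 μ² by default, a mild sequencing-like
  dispersion).
* **Depth-linked sensitivity** (`generate_ms_from_depth()`): the
  probability that a full-weight substitution is poorly tolerated rises
  linearly with depth (defaults 0.25/Å with intercept −0.65, making
  polar/charged substitutions lethal at core depths ≥ 6 Å and tolerated
  at the ~3 Å surface), modulated by class weights encoding the burial
  motif (aliphatic 0.05, aromatic 0.5, polar/charged 1).
* **Melt curves** (`simulate_melt()`): the four-parameter sigmoid plus
  Gaussian noise.

What they do **not** emulate — and hence what passing tests do not show
about real data: real side-chain geometry and rotamers (contacts are
CB/CG-mediated), loops and irregular secondary structure, sequencing
artefacts beyond overdispersion (index hopping, jackpot clones),
position-dependent mutational biases, and any thermodynamic relation
between a substitution and its true ΔΔG. Results on reference
structures therefore remain the decisive external check where those
files are available.

## Problem sizes and numerical conventions

The bundled analyses and the acceptance script use problem sizes chosen
to exercise every code path at interactive cost: a 64-residue ring
bundle with 6 planted constraints and 150 decoys spanning ~0.4–8 Å RMSD
for ContactScore; a 98-residue packed globule with 30 decoys for the
surface/depth-based scores (those profiles are the expensive step);
50 seeds × 100 mutants for read-count round trips; 200 replicates for
melt fits. Determinism throughout: generators save and restore the
global RNG state, so they are pure functions of (arguments, seed);
sphere points are deterministic; rank ties between models are broken by
model id; altloc ties by the first-listed conformer. Degenerate inputs
fail loudly and early — empty structures, zero-variance correlation
inputs, flat melt traces, positions missing from a model — rather than
propagating NAs.

## Known limitations

* The depth algorithm is a surface-point approximation; absolute depths
  differ from water-placement implementations by up to the point-grid
  resolution, so only orderings and correlations should be compared
  across methods.
* The hydrogen-bond criterion is distance-only; a geometric definition
  with angular terms would exclude fewer candidate positions.
* Contact maps treat positions by author numbering unified across
  chains; heteromeric complexes with diverging numbering per chain are
  out of scope.
* With only a handful of constraint pairs, ContactScore saturates for
  models below ~2 Å RMSD; it ranks model *sets*, not near-native
  refinement.
* The R_s reference is only as good as the structure set it is computed
  from; with the synthetic calibration used here it demonstrates the
  statistic, not a database-grade packing reference.
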