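---
title: "Profile hashing and linear-time consensus ranking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile hashing and linear-time consensus ranking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profclust)
```

# The problem

Structure prediction and molecular simulation routinely produce ensembles of
thousands to millions of candidate 3D models ("decoys") of one protein or
RNA molecule.  Two recurring tasks are model quality assessment (MQA) --
ranking decoys by how likely they are to be near the unknown native
structure, usually by geometric consensus -- and clustering, to map the
sampled conformational space.  Both classically require comparing all pairs
of models (superposition RMSD, contact-map overlap, ...), which is quadratic
in ensemble size in both time and memory and quickly becomes the bottleneck.

profclust sidesteps the pairwise loop by projecting each 3D model into a 1D
*structural profile* -- a vector of discrete states -- and doing all
consensus computations on profile state frequencies, which takes one linear
pass.  Profile *hashing* then turns the same machinery into clustering
heuristics whose cost is linear in the number of models.

# Structural profiles

A profile assigns one state out of a small alphabet to each position:

* **SS-SA** (`ss_sa_profile`): per residue, DSSP secondary structure
  collapsed to helix/strand/coil crossed with binned relative solvent
  accessibility.  With the default 10 accessibility bins the alphabet has
  3 x 10 = 30 states.  DSSP output is ingested from files
  (`read_dssp`); accessibilities are normalised by the Tien et al.
  theoretical maximum ASA per residue type (a fixed, documented scale) and
  clipped to [0, 1], with equal-width binning and the top edge closed.
* **CA(SS)-NC(SA)** (`ca_ss_nc_profile`): a coordinate-only analogue for
  CA traces.  Residue i is helix-like when d(CA_i, CA_i+3) < 6.0 A,
  strand-like when d(CA_i, CA_i+2) > 6.2 A, else coil; an ideal
  alpha-helix (rise 1.5 A, radius 2.3 A, 100 deg/residue) has
  d(i, i+3) ~ 5.05 A and an extended chain d(i, i+2) = 7.6 A, so the two
  thresholds cleanly separate ideal geometries.  They are stand-in values
  chosen for exactly that property, and are configurable.  The second
  coordinate is the contact number (neighbours within 10 A, excluding
  |i-j| <= 2), capped into unit bins.
* **CA-CM / RNA-P-CM** (`ca_cm_profile`, `rna_p_cm_profile`): the upper
  triangle of the long-range binary contact map as a profile over pair
  positions (i, j), j - i >= 12, enumerated row-major; state 1 iff the
  CA-CA (or P-P) distance is strictly below 8.5 A (15.5 A for RNA
  phosphorus).  Profile length is (L-12)(L-11)/2.
* **RNA-SS-LW / RNA-SS-TA** (`rna_ss_lw_profile`, `rna_ss_ta_profile`):
  stem/loop secondary structure crossed with the 15-class coarse-grained
  Leontis-Westhof base-pair taxonomy (30 states; unpaired residues carry
  the catch-all "Other") or with 5 backbone torsion states (10 states).
  Both are ingested from annotation tables, not computed from coordinates.
  The exact 15-label LW set is configurable at ingestion, since published
  coarse-grainings differ in which rare categories they keep.
* **FragBag** (`fragbag_profile`): a length-independent bag-of-fragments
  encoding -- each backbone window is assigned to its nearest library
  fragment by Kabsch RMSD (ties to the lowest fragment index) and the
  counts form a fixed-dimension frequency vector.  Small synthetic
  libraries are used in the tests; real 400-fragment protein or 92-fragment
  RNA libraries load through the same `read_fragment_library` format.
* **User profiles** (`read_user_profiles`): any externally computed state
  profile via a TSV with a declared alphabet.

All coordinate-derived profiles are rigid-motion invariant by construction
(they depend only on internal distances), which the suite asserts under
random rotations.  Composite states are encoded as
`ss_index * n_bins + bin`, a bijection that round-trips through the
alphabet labels.

# The 1D-jury consensus score

For N aligned profiles of length L over S states, let `counts[p, s]` be the
number of models in state s at position p (the *state frequency table*,
one pass, O(N L)).  The jury score of model m is

    score(m) = sum_p counts[p, state_m(p)]
             = sum_{m'} #{p : state_m(p) = state_m'(p)}
             = N*L - sum_{m'} Hamming(m, m'),

i.e. the total pairwise agreement of m with the whole ensemble (self
included -- the self term is the constant L and never changes the ranking),
computed without the O(N^2) pairwise loop.  The top-scoring model is the
consensus reference; ties resolve by input order so results are
deterministic.  For frequency profiles the same trick applies with cosine
similarity: scores are `u_m . sum_m' u_m'` over unit-normalised vectors
(`jury_rank_frequency`), because cosine handles the large norm differences
between structures of different sizes better than Hamming.

The suite verifies the implementation against an explicit all-pairs
match-count oracle on hundreds of random instances, and checks the timing
grows linearly in N at fixed L.

# Profile hashing

Each model's *hash key* is the binary disagreement pattern with the jury
reference profile: bit p is 1 iff the model differs from the reference at
position p (`make_hash_keys`).  The key popcount is therefore exactly the
Hamming distance to the reference, and the reference minimises the total
key weight over all candidate references by construction.  Models with
identical keys form *micro-clusters* (`group_by_key`; exact bit-pattern
equality, no locality-sensitive approximation).  Frequency profiles join
this machinery after monotone count quantization (`quantize_frequency`,
default bins 0, 1, 2-3, 4-7, >= 8; the discretisation used for hashing
frequency profiles is not pinned down in the literature, so the edges are
configurable).

For binary contact-map profiles the key transform is a bijection, so the
number of distinct patterns is the same for every reference; for
multi-state profiles the binary collapse can merge patterns differently
under different references.  Our own measurements on balanced planted
fixtures show the jury reference does *not* consistently give fewer
distinct patterns there, so the granularity advantage of the consensus
reference should be expected on contact-map-like (binary) profiles rather
than low-noise multi-state ones.

# Clustering heuristics

All three heuristics take the (K, F) contract: K target clusters that
should jointly contain at least F per cent of the models, with F compared
at a 0.5-point tolerance.

**Hash(K, F)** (`hash_cluster`) starts from exact-key micro-clusters and
coarsens key granularity by deleting key positions in order of decreasing
bit entropy (the most variable positions first, ties to the lowest index),
regrouping after each deletion, until the K largest groups reach F% or no
informative positions remain (best coverage seen is then returned).
Deleting a zero-entropy position never changes the grouping, so the loop
stops early once only constant positions remain.  A caveat our planted
fixtures expose: with *balanced* equal-size clusters the
cluster-discriminating positions have bit fractions near 1/3-2/3 and hence
near-maximal entropy, so entropy-ordered deletion removes them before the
quieter noise positions and merges true clusters before coverage is
reached.  The rule favours data where minority clusters are small (their
discriminating positions then have low entropy) or where noise flickers
near 50%; on balanced synthetic fixtures `rpart_cluster` is the better
choice, and the corresponding recovery check in the test-suite documents
the failure honestly rather than hiding it.

**Rpart(K, F)** (`rpart_cluster`) is reference-based partitioning on hash
keys.  A pass at integer radius r grows up to K spheres: the first around
the jury reference's key; each next centre is the unassigned model with the
highest global jury score among those within 2r of the original reference
(when that shell is empty the candidate pool falls back to all unassigned
models, so K clusters stay reachable).  Two design points deserve note.
First, each sphere uses the pass radius r itself: re-deriving the radius
from the new centre's distance to the original reference cannot tighten it
below r (every unassigned point already lies beyond r from the original
reference) but can inflate it to the inter-cluster distance, in which case
one sphere swallows other equidistant clusters -- we measured exactly that
failure on planted fixtures and therefore fixed the radius at r.  Second,
the outer search over r is an integer lower-bound bisection on [0, D_max]
started at ceil(D_max / 4) (one quarter of the maximum key distance from
the reference): it returns the smallest radius whose coverage reaches F,
or the best coverage seen when F is unreachable.  Radius 0 is included so
that K >= N with all-distinct profiles yields exact-key singletons -- the
degenerate limit the Tree heuristic relies on.

**Tree** (`tree_cluster`) is approximate hierarchical clustering: seed
micro-clusters with Rpart (default) or Hash at a large K (`k_micro`,
default 1000) and F = 100, compute the within-group 1D-jury centroid of
each micro-cluster, and run traditional agglomerative average-linkage
clustering on centroid-to-centroid distances (Hamming for state profiles,
cosine for frequency profiles, Kabsch RMSD on centroid coordinates).  The
agglomerator is written in-package (Lance-Williams updates with a cached
row-minimum search): the default is *unweighted* over centroids, i.e. each
micro-cluster counts once regardless of size, matching the
centroid-level reading of "traditional average-distance agglomeration";
`weighted = TRUE` uses micro-cluster sizes as Lance-Williams weights.  The
globally closest pair is always merged next with ties broken towards the
lowest leaf indices, and leaves are ordered canonically by their first
member's input position, so dendrograms are fully deterministic.  Cutting
(`cut_dendrogram`) removes the k-1 highest merges and propagates leaf
labels to members.  When every model is its own leaf the result equals
full average-linkage clustering exactly (heights to 1e-9), which the suite
checks against an independent direct implementation, and against
`stats::hclust` on tie-free distances.

**K-medoids** (`kmedoids_cluster`) is the baseline comparator: PAM-style
alternating assignment/update over an explicit distance matrix (Hamming,
cosine or RMSD -- a medoid formulation because none of these admits a
coordinate mean), with `nstart = 10` seeded restarts keeping the
lowest-cost solution, the usual guard against local optima.  Everything is
deterministic given the seed.

**Evaluation utilities.** `rand_index` scores partition agreement as the
fraction of item pairs co-clustered or separated in both labelings.
`evaluate_selection` implements the two MQA selection rules: the top
selection is "good" when its best quality is within a gap (default 0.2,
the usual MaxSub margin) of the best model in the set, and the
RMSD-to-native of a clustering is the minimum over the centroids of its
top 5 largest clusters.

# Structure similarity kernels

`kabsch_rmsd` computes the least-squares optimal superposition via SVD of
the 3x3 covariance with the determinant sign correction, so reflections are
excluded and chirality preserved; degenerate (colinear) point sets still
return a proper rotation.  `maxsub` seeds every contiguous 4-residue
window, grows the matched set over 4 refinement rounds with the distance
threshold rising linearly to d0 = 3.5 A (re-superimposing on the matched
set each round), and scores the best set as
`sum_i 1/(1 + (d_i/d0)^2) / L`; identical structures score exactly 1, and
one residue displaced far away out of ten gives exactly 0.9.  All four
MaxSub parameters are configurable.

# Synthetic data generators

The generators are first-class, tested code and define the study
conditions of the test-suite.

`generate_ensemble` emulates a decoy set drawn from a few distinct
conformers: each of `n_clusters` base conformers is an independent smooth
deformation of a template trace -- a rigid hinge rotation at a random
interior residue plus a low-frequency sinusoidal bend, with overall
magnitude `conformer_shift` -- and each member adds i.i.d. Gaussian
coordinate noise of sd `noise_sigma`.  The hinge-plus-bend deformation was
chosen because it changes both long-range contacts and RMSD coherently, the
way alternative experimental conformers of one protein differ.  The
headline concordance experiment uses a 60-residue compact template
(`template_trace`, a serpentine slab with near-ideal 3.8 A virtual bonds,
rich in |i-j| > 11 contacts), 3 conformers of 1000 models each,
`conformer_shift = 8` A and `noise_sigma = 0.5` A -- shifts far above the
noise, as for distinct conformers sampled with thermal-scale jitter.

`generate_profile_set` plants `n_clusters` random archetype profiles and
resamples each member position to a uniformly random *other* state with
probability `flip_prob`, so the expected member-archetype Hamming distance
is exactly L x flip_prob (Monte-Carlo checked).  The recovery tests use
flip_prob = 0.05 on L = 60, S = 4 -- archetypes ~45 positions apart versus
~3 flips per member.

What the generators deliberately do not emulate: unbalanced cluster sizes,
quality gradients within clusters (real decoy sets are denser near the
native basin), chain-break artefacts, position-correlated noise, and
missing atoms.  Passing recovery tests therefore demonstrate correctness of
the algorithms under clean planted structure, not MQA performance on real
decoy sets, which depends on external benchmark data.

# Numerical and interface conventions

* Contact cutoffs are strict (`<`); accessibility and contact-number bins
  clamp their top edge; state indices are 0-based internally and labels
  appear only at I/O boundaries.
* All randomised functions take an explicit seed and run on a private RNG
  stream, restoring the caller's RNG state.
* Ties everywhere (jury ranking, medoid assignment, fragment assignment,
  linkage, entropy ordering) break towards the lowest index / earliest
  input order; reruns are byte-identical, and the pipeline commands stamp
  outputs with the tool version and a config hash.
* PDB I/O delegates to bio3d (first altloc kept, insertion codes honoured
  in ordering); residues are aligned positionally, ignoring author
  numbering, because fixed-length profile comparison requires positional
  identity.  A plain whitespace xyz table is supported as a lightweight
  alternative.

# Problem sizes

The test-suite exercises the jury oracle on 200 random instances up to
N = 200, L = 100, S = 30; hash-key invariants on 10,000 profiles; the
degenerate tree equality on 50 instances up to N = 60; planted-recovery
fixtures of 300 profiles and of 180 x 50-residue conformer ensembles; and
the tree-versus-full concordance on a 3,000-model, 60-residue ensemble
(1176 contact-map positions), the scale at which `scripts/acceptance.R`
recomputes the headline Rand index.  These sizes keep the full suite in the
minutes range on one CPU while still separating linear from quadratic
behaviour.

# Known limitations

* Annotation-based profiles ingest DSSP/RNA annotation files; the external
  assignment programs themselves are not executed.
* Hash(K, F)'s entropy rule degrades on balanced planted clusters (see
  above); prefer Rpart seeding there.
* The Rpart radius search assumes coverage is (approximately) monotone in
  the radius; the best-coverage fallback covers non-monotone cases but may
  then overshoot F.
* mmCIF, DCD trajectories, ligands and hydrogens are out of scope for the
  readers; MaxSub is implemented for equal-length model pairs only.
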