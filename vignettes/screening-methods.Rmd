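---
title: "Methods: multi-representation similarity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-representation similarity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

`triscreen` implements ligand-based virtual screening for the small-panel
regime: a reference panel of known actives (tens, not thousands), a
screening library of candidate compounds, and no activity labels to train
on. The method ranks library compounds by similarity to the panel under
three complementary molecular representations and filters the ranking so
that exact rediscoveries of panel members are rejected — the screen's
purpose is novel analogues, not lookups. Combining a text-like substructure
embedding, a 2D pharmacophore fingerprint and a 3D shape descriptor guards
against the failure mode of any single representation: two compounds can
share a fragment vocabulary yet differ pharmacophorically, or match in 2D
while occupying different shapes.

The pipeline is `pretrain` (corpus → embedding model) followed by `screen`
(library + references + model → ranked candidates), both available as R
functions (`cmd_pretrain()`, `cmd_screen()`) and through the
`inst/cli/triscreen.R` command-line wrapper.

## Representations

### 1D: substructure sentences

Each heavy atom contributes one identifier per radius 0..R describing its
circular environment, computed by iterative invariant refinement (element,
charge, total H count, heavy degree, bond-order sum, aromaticity; then
hashes over sorted neighbour (bond, invariant) pairs) and hashed with
FNV-1a. Tokens are emitted atom-major with radii interleaved, so a molecule
with n heavy atoms yields n(R+1) tokens. Bonds between two aromatic atoms
are labelled aromatic rather than by their kekulé order, making sentences
independent of the engine's kekulisation choice. The default radius R = 1
is the standard choice for substructure embeddings: radius 2 environments
are so specific that a desk-scale corpus cannot populate their
co-occurrence statistics.

The embedding is skip-gram with negative sampling (dimension 100, window
10, 5 negatives, 5 epochs, learning rate 0.025 decaying linearly per
epoch), trained strictly sequentially with an internal xorshift PRNG so a
fixed seed reproduces the vector matrix bit for bit. `min_count` defaults
to 1 because desk-scale corpora are small; raise it on large corpora. A
molecule vector is the *sum* of its token vectors — additivity over
sentence concatenation is exact by construction, and the test suite asserts
it to 1e-10 per component. Out-of-vocabulary tokens are skipped (they
contribute nothing); a wholly out-of-vocabulary molecule yields the zero
vector, which the similarity kernel treats as missing-equivalent (score 0
with a warning). The `zero_vector` policy is offered only so ablations can
count OOV explicitly; it is numerically identical.

### 2D: pharmacophore pairs

Atoms are typed by rule: donors are N/O bearing hydrogen; acceptors are O,
or N with an available lone pair (not pyrrole-type N–H, not quaternary);
aromatic atoms carry the flag recovered from the canonical SMILES;
hydrophobes are aliphatic carbons with no N/O/P/S neighbour, plus heavy
halogens; pos-ionizable covers formal cations and basic (non-amide,
non-aromatic) amines; neg-ionizable covers formal anions and carboxylic
O–H. Every unordered pair of typed atoms, with its topological distance
binned at 1–7 and ≥8 bonds, is hashed into 2048 positions and the on-bit
set compared by Tanimoto. Pairs (not triples) are used: with 6 types and 8
bins the raw feature space (168 cells) is already informative at desk
scale, and triples would be dominated by sparsity. A molecule with fewer
than two typed atoms has an empty fingerprint; similarity against it is
defined as 0.

### 3D: conformer feature maps

The base geometry is the package's own deterministic embedding: classical
multidimensional scaling of the topological distance matrix scaled by a
1.5 Å mean bond length. This choice is deliberate. The available
force-field builder proved stochastic in every mode (its RNG state drifts
across in-process calls and fresh processes are time-seeded), which would
break the pipeline's reproducibility contract; the MDS embedding is exact,
per-molecule, and independent of batch composition or library order. Its
geometries are topology-faithful rather than physically minimised — an
acceptable trade-off here because the descriptor is a coarse radial
histogram, and the whole feature-map scheme is designed as a swappable
stand-in with a stable interface (`shape3d_scheme()`).

Additional conformers (default `n_conf = 5`) are sampled by rotating each
rotatable bond — single-order bridge bonds with heavy neighbours on both
sides — by angles from a Park–Miller stream seeded with
`global_seed XOR hash(compound_id)`, so a compound's conformer set does not
depend on where it sits in the library. Each conformer's typed atoms
deposit Gaussian-weighted mass (σ = 0.5 Å) into 8 radial shells of 0.5 Å
around the feature-point centroid, per feature type (48-length vector);
mass beyond 4 Å accumulates in the outermost shell. Conformer vectors are
averaged and unit-normalised. Rigid molecules are unaffected by `n_conf`
(every sample is the base geometry). Molecules with no typed feature have
no 3D vector; the channel is recorded as missing, never zero, and the
aggregation weights renormalise over the channels that exist.

## Scoring and filtering

Similarity is the dot product of the representation vectors: cosine
(clamped to [0, 1]) for the dense channels, Tanimoto for the sparse one —
the only bounded reading under which the filter's case analysis is
well-formed. Per channel a compound takes its best score over the panel
(`reference_rule = "max"`, the standard ligand-based reading of scoring
"against each" reference; `"mean"` is available). The hyper-space filter
zeroes scores below θ and scores equal to 1, with the equality tested at
1e-9 because the cosine of two identical vectors can deviate in the last
bits. θ = 0.75 by default. Filtered channel scores combine by equally
weighted mean (weights renormalised over available channels; `min` and
`rank_mean` offered for sensitivity analysis), the aggregate passes once
more through the filter, and a compound passes when that filtered aggregate
is ≥ θ and it is not an outlier. The threshold is applied to the combined
score by default; `theta_scope = "per_channel"` requires every available
channel to clear θ instead, since either reading is defensible when scores
are computed per representation.

Outliers are flagged by a robust distance rule: each compound's three
representations are unit-normalised, concatenated (missing channels
contribute zeros) and compared with the reference panel's centroid;
compounds farther than `median + 3.5 × MAD` of the cohort's distances are
excluded from passing. MAD uses the usual 1.4826 consistency constant. If
the cohort is degenerate (MAD = 0) outlier detection disables itself with a
warning rather than flagging everything. K-means cluster labels (k ≤ 8,
seeded) are recorded in the results table for reporting only; no filtering
decision depends on them.

Ties in the ranking break by compound ID ascending; scores are written at
6 decimal places and round-trip exactly at that precision.

## Standardisation and corpus curation

Input SMILES are canonicalised by the pinned engine (OpenBabel via
ChemmineR/ChemmineOB; versions recorded in every run manifest, since
canonical SMILES are not portable across engines). Standardisation
neutralises formal charges where chemically possible and keeps the largest
organic fragment, so salts and solvates (e.g. a dihydrate) reduce to the
parent molecule; ties on fragment size break toward the lexicographically
smaller canonical SMILES and are logged. Stereochemistry is preserved when
present but never required. The pre-training corpus filter retains
molecules over the organic element whitelist {H, B, C, N, O, F, P, S, Cl,
Br, I} with 3–100 heavy atoms, single fragment, deduplicated on canonical
SMILES; every rule is exposed in `corpus_filter_rules()` and every
rejection carries a reason. Unparsable library entries become
`parse_failed` records and never abort a screen.

## What the synthetic fixtures do and do not show

`fixture_spec()` defines the desk-scale study conditions: a 14-member
reference panel spanning flavonol, stilbenoid, dibenzopyranone, polyamine,
pyridine-amide, macrolactone, salicylate, hydroxycinnamate,
diarylheptanoid, flavanol, indoleamine, aryl-hydrazone and isothiocyanate
chemistry (synthetic stand-ins, chosen for scaffold diversity at small
size); a 192-compound library of 28 planted analogues (single substituent
edits of panel members, mirroring real analogue series such as a flavonol
differing by one hydroxyl), 14 exact duplicates (to exercise the s = 1
rejection), and 150 decoys enumerated from ten scaffolds disjoint from the
panel's; and a 2,000-molecule corpus enumerated from the union of panel and
decoy parents so that library substructure tokens are in-vocabulary and OOV
stays an exercised edge case. Identical specs generate checksum-identical
files; ground-truth labels live in a separate TSV the screen never reads.

Passing tests on these fixtures demonstrate the machinery — duplicate
rejection, threshold monotonicity, enrichment of true analogues over
decoys, determinism — under controlled conditions. They do not demonstrate
screening performance on real chemical libraries: real corpora are orders
of magnitude larger and more diverse, real analogue relationships are
subtler than single substituent edits, and decoys here are deliberately
easy. Problem sizes (2,000-molecule corpus, 192-compound library) are the
package's chosen desk-scale defaults; all scale up through the spec and
config objects.

## Known limitations

* Geometry: the MDS embedding preserves topology, not conformational
  energetics; 3D scores should be read as shape-topology similarity. The
  scheme is interface-stable so a physical conformer generator can be
  swapped in where a deterministic one is available.
* Pharmacophore typing is rule-based, not SMARTS-definition complete;
  tautomer-dependent typing is not attempted.
* Aromatic perception follows the SMILES engine; exotic aromatic systems
  the engine cannot kekulise are dropped at parse time.
* The encoder/decoder architecture sketched alongside the summing rule in
  the original workflow description is unspecified there; only the
  documented sum-of-substructure-vectors model is implemented.
* No InChI input, no reaction SMILES, no depiction, no supervised QSAR.
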