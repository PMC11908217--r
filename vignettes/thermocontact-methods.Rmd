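---
title: "Methods: temperature-sensitive contact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-sensitive contact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocontact)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## The analysis model

The object of study is a protein sampled as conformational ensembles at an
ordered ladder of temperatures, together with its structure and a family
multiple sequence alignment. Every stage reduces to operations on three
per-residue or per-contact summaries:

* **Contact frequency.** For residues *(u, v)* and interaction type *t*,
  the frequency at temperature *T* is the fraction of sampled frames in
  which the geometric criterion for *t* holds for at least one atom pair of
  *(u, v)*. A (pair, type) is counted once per frame no matter how many
  atom pairs satisfy it, and same-chain pairs with |i − j| ≤ 2 in author
  numbering are excluded so that trivially persistent neighbor contacts do
  not dominate the statistics or the networks.
* **Thermal response.** Collecting frequencies over the ladder gives a
  matrix *F* (contacts × temperatures). PCA of *F*ᵀ after centering each
  contact across temperatures yields thermal contact modes.
* **Per-residue features.** RMSF and its across-temperature standard
  deviation (the temperature-sensitivity score), hydrophobic-network
  closeness centrality, and normalized conservation entropy.

## Geometric contact criteria

The trajectory-analysis tools this field uses for contact detection do not
share a single published set of cutoffs, so the package makes its criteria
explicit and configurable (`contact_params()`), with defaults at the
community's de facto values. All criteria act on heavy atoms only, which
makes hydrogen-free crystal structures and trajectory frames behave
identically:

| type | criterion | default cutoff (Å) |
|---|---|---|
| salt_bridge | Arg/Lys/His sidechain N to Asp/Glu carboxylate O | 4.0 |
| hydrophobic | sidechain C of {ALA,VAL,LEU,ILE,MET,PHE,TRP,PRO} pairs | 4.5 |
| hbond | heavy-atom N/O donor–acceptor proxy | 3.5 |
| cation_pi | Arg/Lys cationic-group centroid to aromatic ring centroid | 6.0 |
| pi_stack | aromatic ring centroid pairs | 5.5 |

The hydrogen-bond criterion is deliberately a proxy: without hydrogens no
donor–H–acceptor angle is defined, and adding one would make crystal and
simulation inputs inequivalent. Raising any cutoff can only add contacts
(monotonicity), which the tests assert.

## Thermal modes: centering, orientation, classification

PCA treats temperatures as observations and contacts as variables. Contacts
are centered but *not* scaled to unit variance: frequencies already share
the [0, 1] scale, and unit-variance scaling would amplify noise from
near-constant contacts into the leading components. Contacts with zero
variance across the ladder carry no mode information and are reported
separately as temperature-stable.

PCA leaves a sign ambiguity per component. Each mode is oriented so that
the regression slope of its temperature scores on temperature is
non-negative. Under that convention a contact whose frequency falls with
temperature (melting) must carry a negative loading, and a forming contact
a positive one — so a single mode can hold both groups at its two loading
extremes. This is not an implementation accident but a property of the
linear model: a forming trend is, after centering, the negative of a
melting-shaped trend, so symmetric melting/forming populations load with
equal magnitude and opposite sign on the same component. Consequently:

* `classify_modes()` labels a mode *melting* (or *forming*) only when at
  least 75% of its top-|loading| contacts reconstruct a downward (upward)
  frequency trend against temperature (Spearman), and *mixed* otherwise.
  A matrix planted with melting contacts only gets a melting first mode; a
  symmetric plant honestly gets *mixed*.
* `top_contacts(direction = "melting")` / `"forming"` extracts the signed
  extremes, which is the correct way to recover the two planted groups from
  one mode; the package's tests recover ≥ 18 of 20 of each group this way.

With six temperatures at most five modes exist; the default retains two,
which in practice carry the temperature response.

## Closeness centrality on thresholded graphs

Edges of the hydrophobic graph are contacts whose *mean* frequency across
the full ladder exceeds 0.75 (configurable); the mean is kept as edge
weight for reporting, but shortest paths are unweighted hop counts, because
the centrality definition used,

C_i = (n − 1) / Σ_j d(i, j),

is written in terms of path length alone. Thresholded graphs are often
disconnected, which the plain formula does not address; the package uses
the standard component-scaled generalization
C_i = [(r_i − 1)/Σ d] · [(r_i − 1)/(n − 1)] (r_i = size of *i*'s
component), which reduces exactly to the formula above on connected graphs,
bounds C_i in [0, 1], and gives isolated residues 0. Centrality is computed
on the full graph, not the largest component, so residues outside the core
are scored (low) rather than dropped. The top-centrality subnetwork keeps
the top ⌈fraction · n⌉ residues (default 20%) plus induced edges, ties
broken by residue order.

## RMSF and the temperature-sensitivity score

Frames are rigid-body least-squares fitted to an iteratively refined mean
structure over all polymer Cα atoms (no terminal trimming by default; a
selection mask is available). Refinement stops when the mean moves less
than 10⁻⁶ Å, which takes a handful of passes. RMSF is
√(mean over frames of |x − ⟨x⟩|²) — the population form, averaging over
frames rather than dividing by frames − 1. The temperature-sensitivity
score is the *population* standard deviation of a residue's RMSF across
the ladder: the ladder is the entire set of studied conditions, not a
sample from a larger one. All frames are used by default; a configurable
discard fraction would be the natural extension for equilibration trimming,
which the package does not impose.

## Conservation entropy

Column entropy is computed over the 20 amino acids with gaps excluded and
probabilities renormalized (the default gap policy); a column that is all
gaps has no distribution and is recorded as missing, never as zero (zero
means perfectly conserved). Columns with more than 50% gaps are flagged
low-confidence. Normalization divides by log₂ 20 — a fixed ceiling — rather
than a per-column or per-alignment maximum, so values are comparable across
enzymes and mappable onto structures on one scale.

Pairwise identity/similarity uses global Needleman–Wunsch alignment with
BLOSUM62 and affine gaps (open 10, extend 0.5); identity counts identical
aligned pairs over gap-free aligned positions, similarity additionally
counts BLOSUM62-positive pairs. Published comparisons for the four
subtilisin homologs derive from structure-based superposition alignments,
which this package does not perform; sequence-based global alignment is the
stand-in, so recomputed identities are reported as comparisons, not
asserted to match published values exactly. The dendrogram is UPGMA on
distance = 100 − identity; for multi-chain structures the first polymer
chain is analyzed by default and the choice logged.

## Residue clustering and the elbow rule

The three per-residue features carry incommensurate units (dimensionless
entropy, Å, dimensionless centrality), so they are z-score standardized
before k-means. Residues absent from the hydrophobic graph genuinely have
no core connectivity and receive centrality 0; residues with no mapped MSA
column have no conservation value and are dropped with a logged count.
Clustering uses `stats::kmeans` with 25 random restarts, deterministic
given the seed; reported cluster numbers are ordered by descending mean
temperature sensitivity so that labels are comparable across enzymes
(raw k-means labels are arbitrary).

The WCSS elbow suggestion uses *relative* curvature,
(W(k−1) − 2W(k) + W(k+1)) / W(k), rather than the raw second difference:
raw curvature is dominated by the large early drops of any WCSS curve and
selects k = 2 even when a pronounced bend exists later (on four planted
blobs with WCSS 717, 358, 197, 92, 81, … the raw rule picks 2, the
relative rule 4). Because data with no cluster structure has nearly flat
relative curvature, the suggestion takes the smallest k reaching 75% of
the maximum (parsimony tie-break) instead of the literal argmax. On a
single Gaussian blob this keeps the suggestion at 2 for the large majority
of random realizations; occasional 3–4 suggestions are inherent — a finite
sample of a blob contains real clumps — which is why the suggestion is
reported alongside, not instead of, the full curve. The default k = 4
follows the study design this package supports.

## The synthetic-data generators

The generators exist so that every stage has an oracle, not to imitate
physics:

* `synth_ensemble()` builds a toy polymer on a wide grid (residue anchors
  40 Å apart, beyond every cutoff) and realizes each scheduled contact by
  translating the partner residue so the probe atoms sit inside the
  criterion in exactly the scheduled frames. Frequencies therefore equal
  schedule occupancies *exactly*, which is the point. Because the whole
  partner residue moves, other criteria (e.g. the N/O proxy) may also fire
  for that same pair — additional typed contacts between a scheduled pair
  are expected, and bookkeeping is per scheduled type. Each residue may
  join at most one scheduled contact; conflicting schedules are rejected
  rather than approximated. A small coordinate jitter (0.05 Å) avoids
  bit-identical frames without ever crossing a cutoff margin.
* `synth_contact_ladder()` plants logistic melting curves
  f(T) = 1/(1 + exp((T − Tm)/w)), mirrored forming curves, and constant
  inert rows, with truncated Gaussian noise (σ = 0.02 by default) and the
  six-point 283–393 K ladder as the default study conditions. Midpoints
  are staggered across the inner 80% of the ladder span.
* `synth_msa()` samples columns independently from specified symbol
  distributions, so column entropies converge to the specification as the
  number of sequences grows; the designated query row is the per-column
  mode and gap-free, so structure mapping is exercised too.
* `synth_feature_clusters()` plants Gaussian blobs in feature space with
  known labels.

All generators are pure functions of their specification and a mandatory
seed.

What passing these tests shows: the analysis stack computes its statistics
correctly, deterministically, and at the stated closed forms. What it does
not show: anything about force fields, sampling convergence, solvent, or
the thermodynamic coherence of real ensembles — the toy ensembles have no
physics, the planted ladders impose monotone trends with independent noise
(real contact frequencies are correlated across contacts and temperatures),
and the synthetic MSAs have independent columns (real families have
phylogenetic and covariation structure). Conclusions about a real enzyme
require real ensembles and a real family alignment as inputs.

## Numerical and degenerate-input choices

* Contact keys are canonical (lower chain, then lower residue number
  first), so detection is symmetric in argument order; ties in top-k
  rankings break by canonical key order, making all rankings
  deterministic.
* PCA on a constant matrix is refused ("no temperature-dependent
  variance") rather than returning arbitrary axes.
* A mode with fewer than two varying contacts cannot be classified and is
  labeled mixed with a warning.
* Altloc atoms keep the highest-occupancy conformer (tie: first
  encountered); waters are excluded at parse time; other heteroatoms are
  kept and flagged, and all geometric criteria simply never select them
  unless their names match.
* B-factor projection min–max scales to [0, 99.99] (the PDB column's
  printable range); unmapped residues get 0.
* Problem sizes in tests and the acceptance script (40–80 toy residues,
  tens of frames per ensemble, 10⁴–10⁵ samples for convergence checks,
  50 random graphs of 30 nodes) are chosen so every closed form is
  exercised well inside its sampling-error bound while the whole suite
  runs in well under a minute.

## Known limitations

* No trajectory periodic-boundary imaging or unwrapping: inputs are
  assumed whole-molecule.
* The hydrogen-bond proxy ignores geometry beyond the N/O distance.
* Ensembles are read fully into memory per temperature; the frame-stream
  interface hides this, but very long trajectories should be strided.
* Sequence-based alignment will not exactly reproduce identities derived
  from structural superposition (see above).
* Expanded-ensemble reweighting is out of scope: per-temperature
  frequencies are treated as direct averages of the supplied frames.
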