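---
title: "Designing zinc finger proteins with ensemble micro neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing zinc finger proteins with ensemble micro neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design problem

Cys2-His2 zinc finger proteins (ZFPs) are the workhorse DNA-binding scaffold
of targeted genome engineering.  A three-finger ZFP reads a 9 bp DNA target
as three 3 bp subsites, one per finger; specificity is carried almost
entirely by the recognition helix, the seven alpha-helical residues at
positions $-1, +1, \dots, +6$, of which the *cardinal* residues at $-1$,
$+3$ and $+6$ (together with a fixed $+2$) contact the bases.  `zifnn`
predicts, for an arbitrary 9 bp target, the 21-residue helix triple
(F1+F2+F3) expected to bind it best, under the *synergistic* view of
binding in which a finger's contribution depends on its neighbours rather
than being strictly additive.

Because evaluating every complex is infeasible — $4^9$ targets times $448^3$
helix combinations — the method learns the target-to-helix mapping from a
small, structurally modelled training set and then generalises:

1. **Sampling.** A representative subset of the $4^9 = 262{,}144$ 9-mers is
   chosen by K-means clustering ($K = 50$ in the original design) of their
   one-hot encodings.
2. **Library enumeration.** Candidate helices are generated from the
   Zif-268 template by mutating positions $-1/+3/+6$ over allowed sets of
   sizes 7, 8 and 8 ($7 \cdot 8 \cdot 8 = 448$ helices per finger);
   position $+2$ is kept fixed to eliminate cross-strand interactions.
3. **Energy scoring.** Candidate complexes are ranked by summed
   hydrogen-bond free energy (below); per target, the best-ranked helices
   become the training label.
4. **Learning.** An ensemble of 100 *micro* neural networks — single hidden
   layer, hidden width drawn uniformly from 28..52, an order of magnitude
   below the 420-dimensional output — is trained on the (target, design)
   pairs.  Each net votes one residue per position; the 21×20 vote matrix
   yields a consensus design, exact top-k alternatives, and a confidence
   score $e^{-0.01 s}$, where $s$ is the design's total vote count.

This package implements steps 1, 2 and 4 in full, the energy model of step
3 given externally extracted bond geometries, the evaluation metrics, and a
synthetic generator standing in for the structure-based labelling.
Structural modelling itself (docking, homology modelling, H-bond extraction
from coordinates) is out of scope: the package consumes its products.

## Encodings

Targets are encoded as 36-vectors (nine 4-blocks; A=(1,0,0,0), T=(0,1,0,0),
G=(0,0,1,0), C=(0,0,0,1)) and designs as 420-vectors (21 blocks of 20).
The residue order within a block is not dictated by the method; this
package fixes the alphabetical one-letter order `A,C,D,...,Y` in one
constant used everywhere.  Decoding is per-block argmax with ties resolved
to the lowest index, so it is total on raw sigmoid outputs.

Ambiguous bases (including N) are rejected at input rather than expanded:
a query must commit to one of the $4^9$ concrete targets the model is
defined over.

## Hydrogen-bond free energy

Each bond contributes

$$\Delta G_{hb} = \varepsilon_{ij}\left[3\left(\frac{d'_{ij}}{d_{ij}}\right)^{8}
  - 4\left(\frac{d'_{ij}}{d_{ij}}\right)^{6}\right]\cos^4\theta,$$

with pair-class constants $\varepsilon_{ij}$ (kcal/mol) and $d'_{ij}$ (Å):
N–N (2.0, 3.2), N–O (2.8, 3.0), O–O (4.0, 2.8).  At $d_{ij} = d'_{ij}$ and
$\theta = 0$ the energy is exactly $-\varepsilon_{ij}$; it vanishes at
$\theta = 90^\circ$ and diverges to $+\infty$ as $d_{ij} \to 0$.  The
angle's reference is not fixed by the formula alone; we take $\theta$ as
the deviation from linearity ($0^\circ$ = ideal bond), the only convention
under which the $\cos^4$ factor maximises the magnitude of an ideal bond.
Geometry records arrive as plain TSV (`donor_element`, `acceptor_element`,
`distance`, `angle`); no distance or angle cutoff is applied before
summation — records are taken as the extraction step produced them.
Complex energies are sums over bonds; ranking is ascending (more negative
= stronger predicted binding) with stable ties.

## Sampling choices

The method names K-means but not its metric, initialisation or iteration
policy.  We cluster one-hot encodings under Euclidean distance (on one-hot
vectors this is a monotone function of Hamming distance), initialise with
seeded k-means++, run Lloyd's algorithm to assignment convergence or
`max_iter = 300`, and keep the best of `n_init = 10` starts by
within-cluster sum of squares; all of these are arguments.  An emptied
cluster is re-seeded from the point farthest from its centroid.  Because
the published representatives are actual sequences, each centroid is
snapped to its cluster *medoid* (nearest member, lexicographically smallest
on ties), so representatives are always population members.  Given a seed
the whole procedure is deterministic.

We make no attempt to reproduce the original 50-sequence set — its seed and
initialisation are unknowable — but the published set ships as
`inst/extdata/representative_targets.tsv` for use as a fixture.

## The ensemble and its hyperparameters

Each micro net computes `Sigmoid(W2 . [Sigmoid(W1 . [x; 1]); 1])`; the
constant-1 entries implement biases while preserving the plain
`Sigmoid(W.X)` layer form.  Training minimises the squared output error by
per-sample stochastic gradient descent (batch size 1), reshuffling the
sample order each epoch, for 150 epochs.  Unstated details are fixed as
package defaults, all configurable:

* **Weight initialisation**: uniform in $[-0.5, 0.5]$, seeded.
* **Learning rate**: 0.5 on the exact gradient of the summed squared error.
* **Hidden width**: uniform integer on $[28, 52]$ inclusive, drawn under
  the master seed.
* **Seeding**: net $i$ trains under `seed + i`, so training is
  embarrassingly parallel and independent of scheduling order.

The per-query vote matrix tallies each net's decoded design
position-by-position; rows always sum to the ensemble size.  The consensus
takes the per-position plurality (alphabetically first residue on exact
vote ties).  Because positions are scored independently, the consensus
vote total is provably maximal over all $20^{21}$ candidate designs, and
the top-k list can be produced *exactly*: a best-first search over
single-position downgrades, ordered by vote total with lexicographic
tie-breaks.  This exact decoding is the only top-k rule consistent with
ranking candidates by the score $e^{-0.01 s}$.  Ten predictions per query
are reported by default.

## What the synthetic generator emulates — and what it does not

The original training labels come from docking: for each sampled target,
the helix triple with the best interface energy.  Our generator replaces
that physics with a deterministic *recognition code*, matching the
structure of the mapping rather than its energetics:

* **Modular component.**  The Cys2-His2 code is, to first order,
  base-wise: position $-1$ reads the subsite's 3' base, $+3$ the middle
  base, $+6$ the 5' base.  For each finger the generator draws a seeded
  per-base residue code at each key position from the allowed-mutation
  sets and composes a subsite's helix from the three base codes — so every
  emitted helix is a member of the 448-helix library, and the map is a
  deterministic function of the subsite.  (An earlier design that assigned
  an arbitrary random library helix to each 3-mer was rejected: it has no
  counterpart in real protein–DNA recognition, and its fully entangled
  3-mer dependence is dominated by single-occurrence subsites that a
  40-example training set cannot pin down.)
* **Synergy surrogate.**  With probability `coupling`, a (finger, 3-mer)
  entry instead carries one independently drawn helix per first base of
  the neighbouring subsite.  At `coupling = 0` the code is purely modular;
  at `coupling = 1` every subsite is context-dependent.  This surrogate is
  an artifact of the generator, chosen to give datasets the qualitative
  signature of synergistic binding (identical subsites labelled differently
  in different contexts); it does not model the physics of cooperativity.
* **Noise.**  Each key-position residue is independently corrupted with
  probability `noise_rate` to a *different* residue from that position's
  allowed set (singleton sets leave nothing to corrupt to).  Non-key
  positions are template-fixed and never corrupted.
* **Scale.**  Defaults mirror the published design: 50 targets drawn
  uniformly without replacement from the $4^9$ space, split 40 training /
  10 testing.

Consequently, passing tests on synthetic data show that the *learning
machinery* behaves as specified — memorisation of a consistent code,
vote conservation, generalisation across subsites under a modular code —
not that the method attains any particular accuracy on docking-derived or
experimentally characterised complexes.  Evaluation against real data goes
through the packaged benchmark of 16 literature-curated targets instead.

Finger orientation follows the canonical Zif-268 antiparallel convention
(F1 binds the 3'-most subsite); the parallel reading is available as
`orientation = "5prime"` since printed comparison tables do not
disambiguate the convention.

## Evaluation metrics

Accuracy is position-wise sequence identity, `matches/21`
($= 1 - d_H/21$).  Two display conventions coexist in the printed
literature this package reproduces: per-row table cells are *truncated* to
two decimals ($17/21 = 0.8095 \to 0.80$), while prose percentages are
*rounded* ($0.8095 \to 81\%$); `identity_display()` and
`percent_display()` implement the two, and reports always average the
unrounded fractions.  Coverage is the fraction of benchmark targets for
which a tool returned any prediction.  Consensus-pattern matching
(`matches_consensus()`) supports `N` wildcards and `X/Y` alternations.

## Numerical and degenerate-input choices

* All argmax ties (decoding, consensus, clustering assignment) resolve to
  the lowest index; k-best ties on equal vote totals order
  lexicographically by design string.  Everything downstream of a seed is
  bit-reproducible, and no code path draws from OS entropy or wall-clock.
* An empty bond table is a valid complex with energy 0; `rank_designs()`
  is a stable sort, preserving input order among exact ties.
* `enumerate_population()` is capped at 9-mers (262,144 sequences) to
  guard against accidental memory blowup; the design-space iterator
  streams $448^3 \approx 9\times10^7$ candidates in constant memory.
* Requesting more top-k predictions than distinct candidates returns all
  candidates with a warning and a `truncated` attribute.

## Problem sizes used by the shipped tests and acceptance script

The test suite exercises the full published operating point once — 100
networks, hidden 28–52, 150 epochs, 40 noise-free pairs — and otherwise
uses reduced ensembles (3–30 nets, 2–150 epochs, 5–12 pairs) and toy
clustering spaces (dimers/trimers) where the property under test does not
depend on scale.  The acceptance script re-runs the full operating point,
K-means at $K=50$ over the complete 9-mer space (single start, up to 100
Lloyd iterations), and recomputes every benchmark identity from the
packaged sequence pairs.

## Known limitations

* The allowed-mutation sets shipped as defaults are a clearly labelled
  stand-in assembled from commonly reported recognition-code residues; the
  original per-position lists were published only as supplementary
  material.  Only the set *sizes* (7/8/8) matter to any count or test, and
  the table is overridable from YAML.
* The hydrogen-bond model omits solvation, van der Waals, hydrophobic and
  electrostatic terms by design, and trusts the upstream geometry
  extraction (no cutoffs, no hydrogen placement, no PDB parsing).
* The ensemble offers no regularisation or early stopping — none are part
  of the method — so labels inconsistent with any deterministic code (high
  `noise_rate`, strong coupling with sparse coverage) degrade predictions
  with no safeguard beyond the confidence score.
* Reverse-complement equivalence of targets is deliberately not inferred;
  a query and its reverse complement are distinct inputs.
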