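---
title: "Route-based rewards: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Route-based rewards: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthreward)
```

This vignette is the package's own account of the science behind its four
reward functions: what each one models, which parameters matter, how the
numerical corner cases are resolved, and where the design was genuinely
open and a choice had to be made.

## Route trees and their annotations

A retrosynthetic route is a rooted tree: the root is the target molecule,
internal nodes alternate between molecules and reactions, and leaves are
precursor molecules. Every reaction node carries a hierarchical taxonomy
code — `X` (superclass), `X.Y` (class), `X.Y.Z` (named reaction), e.g.
`3.1.2` for a chloro Suzuki coupling. A route is *solved* when every leaf
is available in the stock catalog (internally or commercially); routes that
stop at unavailable intermediates are retained as unsolved, because some
rewards can still use them.

Two resolutions of the taxonomy are used deliberately. The feasibility
reward matches preferred reactions at whatever level the user supplies
(class-level entries such as `3.1` admit all named Suzuki variants), giving
fine control where it is wanted. The batch-level rewards operate on
*route signatures* — the set of class-level codes in a route — because a
parallel-synthesis plate tolerates named-reaction variation within a class
but not a change of chemistry.

Corner cases are resolved as follows, and these choices propagate through
everything downstream:

* A reaction whose classification is missing or unparseable is coded with
  the sentinel `0.0`. Parsing never fails on it; any signature containing
  it is invalid and scores 0 in the intrinsic rewards.
* A zero-step route (target already in stock) has the empty signature,
  which is treated as invalid for the intrinsic rewards — a "plate" of
  purchasable compounds is not a synthesis plate — while the feasibility
  reward handles the same route gracefully through its empty products
  (stock and reaction factors 1, step factor $k^0 = 1$).
* Step count is the number of reaction nodes, not tree depth: a convergent
  route with two one-reaction branches under the root reaction counts
  three steps, which is what a chemist would call it.
* Identifier comparison applies exactly one normalization, whitespace
  trimming, identically to catalogs and route documents. Nothing else is
  inferred about identifiers; SMILES are treated as opaque strings.

## Feasibility: SFScore

$$S(t) = \prod_{p \in P(t)} \mathrm{stock}(p) \times
         \prod_{r \in R(t)} \mathrm{react}(r) \times k^{n(t)}$$

Defaults: internal 1.0, commercial 0.8, unavailable 0.1; preferred
reactions 1.0, others 0.1; $k = 0.9$. All factors live in (0, 1], so the
score degrades multiplicatively as any component becomes limiting: a
three-step, all-internal, all-preferred route scores $0.9^3 = 0.729$; one
commercial and one unavailable leaf alone pull the stock factor to 0.08.
A molecule takes the maximum over its trees — its *best* route is what a
chemist would actually run — and a molecule with no routes at all scores 0:
a generator should not be rewarded for unroutable molecules. Unsolved
routes are scored by default (their unavailable leaves already cost 0.1
each); `use_unsolved = FALSE` restricts to solved ones, and `max_steps`
optionally drops long routes at score time, so the same parsed trees can be
re-scored under different project constraints. Stock status is looked up in
the catalog at score time rather than from parse-time flags for the same
reason: swapping a catalog must re-score correctly.

## Reference-route similarity: RRScore

Routes are first reduced to canonical ordered trees of reaction labels.
Molecule nodes are elided — the reaction pathway is the object of
comparison — and children are sorted by a deterministic recursive key, so
two documents listing branches in different orders map to the same tree.
That canonicalization is what justifies using the *ordered*-tree edit
distance (the Zhang–Shasha dynamic program, exact for ordered labeled
trees): unordered tree edit distance is intractable in general, and after
canonical sorting child order carries no chemical information.

The cost scheme makes distances chemically graded: deletion and insertion
cost 4.0; renames cost 3.0, 2.0 or 1.0 by the taxonomy depth of the first
disagreement. Rename never exceeds delete + insert (enforced by the
constructor), so renaming is never trivially dominated. Two rules extend
the scheme to awkward labels deterministically: components absent from both
codes compare equal while absent-vs-present counts as a disagreement at
that depth (so `2.1` vs `2.1.10` costs 1.0), and the `0.0` sentinel differs
from every real code at the superclass level.

The distance of the best solved route is mapped to a similarity. The
transform is constrained to map 0 to 1 and decrease strictly toward 0; the
default is the reciprocal $1/(1 + d/\mathrm{scale})$ with scale 1, and
$\exp(-d/\tau)$ is available as a configuration alternative. Both satisfy
the constraints; the reciprocal keeps a heavier tail, which preserves
gradient far from the reference early in a run. Molecules with no solved
route score 0 — similarity to a reference you cannot reach is not rewarded.

The package also ships `brute_force_ted()`, an exhaustive enumeration of
valid edit mappings for trees of at most six nodes. It exists purely as an
independent oracle: the test suite checks the dynamic program against it on
hundreds of seeded random tree pairs.

## Route popularity

Within a batch of $N$ molecules, a signature $S$ carried by the solved
routes of $|M_S|$ distinct molecules has popularity $|M_S|/N$, and molecule
$i$ scores $Q_i = \max_S |M_S|/N$ over its own solved-route signatures.
Only solved routes count — batch coherence on routes nobody can run is
worthless — and each molecule counts once per signature however many of its
routes share it. The maximum of $Q_i$ over the batch equals the largest
cohort fraction, a useful logged metric (`dominant_fraction` in the
simulator) even in runs that do not optimize it.

## Fill-a-Plate and the ledger

The plate ledger is the cross-batch state: per-signature cumulative counts
of distinct assigned molecules, the saturated set, the consumed set, and
the molecule-to-plate assignment. Capacity defaults to 1000 molecules per
plate at full scale. Three decisions here were genuinely open and are worth
recording:

* **Assign-then-score.** A molecule's reward is the filling ratio *after*
  its own assignment. Scoring before assignment would give every new
  signature a hard 0, and a reward that zeroes everything it has not seen
  cannot bootstrap exploration; with assign-then-score the first molecule
  of a fresh plate earns $1/C$ — tiny but nonzero.
* **One plate per molecule per batch.** Among a molecule's valid,
  unsaturated signatures, the one with the highest current count is chosen
  — the plate closest to threshold — and only that count is incremented. A
  molecule never part-fills several plates at once, which keeps the
  conservation law (sum of counts = distinct assigned molecules) exact.
* **Determinism at ties.** Equal counts break to the lexicographically
  smallest signature key. Any fixed rule would do; this one needs no state.

Saturation is irreversible and silent: a full plate's signature scores 0
from then on. With exclusion enabled, its molecules are consumed and score
0 everywhere afterwards, so no molecule sits on two plates; duplicates of
already-assigned molecules never re-increment a count (the counts track
*unique* molecules), scoring their plate's current ratio without exclusion
and 0 with it. The ledger round-trips through a small JSON document so runs
can be resumed across processes.

## Combining rewards

`combine_scores()` is the weighted geometric mean
$(\prod v_i^{w_i})^{1/\sum w_i}$ with values clipped to [0, 1]. A zero
value with positive weight annihilates the result — deliberate hard-filter
semantics, with no epsilon flooring, so "this molecule has no solved route"
zeroes the whole reward rather than being averaged away. A weight of zero
removes a component from the product while its value is still computed and
logged; that is the entire mechanism behind control runs.

## The simulator: what it emulates, and what it does not

The desk-scale simulator replaces a sequence-model generator plus a
retrosynthesis planner with the smallest system that can respond to these
rewards: a multiplicative-weights bandit over eight *route archetypes*.
Each archetype draws 1–3 reaction steps from a six-code pool spanning three
reaction classes (so its class signatures are the non-empty subsets of
three classes — up to seven plates per archetype), has a solvability
probability (0.8–0.9), a 4% chance per step of losing its classification,
and a surrogate property score drawn from a Beta distribution whose mean
differs by archetype. One archetype emits the fixed two-step reference
chain `2.1.10 → 3.1.2` with occasional named-level variants. Molecule
identities come from a finite per-archetype pocket of 3000 candidates,
unique within a batch but reusable across batches: a policy that
over-exploits one archetype starts regenerating duplicates, which is
exactly the failure mode the batch-level rewards are designed to expose,
and the only way the ledger's unique-molecule and exclusion semantics are
ever exercised by a loop.

Per epoch the loop samples a batch (size 128), computes the active reward,
combines it with the surrogate property score at equal weight (weight 0 on
the active component in control runs, which therefore drift on the
property signal alone — by construction toward the archetype with the
highest property mean), updates the policy by
$w_a \leftarrow w_a e^{\mathrm{lr}\, \bar r_a}$ with learning rate 2, and
logs metrics. Popularity fractions and the plate ledger are computed in
every run regardless of the active reward, so control runs log the same
synthetic metrics they do not optimize. Default desk dimensions — 128
molecules per batch, 200 epochs, plate capacity 50 — keep a full run in
seconds while leaving room for dozens of plates to fill; the acceptance
checks use 40-epoch triplicates, enough for all three directional effects
to saturate. All randomness derives from one master seed (per-epoch batch
seeds are a fixed affine function of it), so runs are bit-reproducible.

What passing these tests shows is *directional*: reference-route runs end
with a lower mean edit distance than they start, popularity runs end more
batch-coherent than control, plate-filling runs fill strictly more plates
than control. What they cannot show is anything about real chemistry: the
simulator has no molecules, no reaction feasibility, no property landscape
— its archetypes are caricatures with hand-set probabilities, its policy is
an eight-armed bandit, and absolute magnitudes (hit counts, plate counts,
distances) are artifacts of those settings. Claims about real generators
require the full planner-and-generator stack these rewards are designed to
plug into.

## Known limitations

* Reaction classification is consumed as annotation; the package never
  predicts classes from structures, and routes lacking annotations
  degrade to invalid signatures rather than being reclassified.
* The edit distance compares reaction pathways only; if molecule-node
  identity should ever contribute to route similarity, the comparison
  trees would need a second node type and a corresponding cost extension.
* Identifier canonicalization is whitespace trimming only; two different
  SMILES strings for the same molecule are different identifiers here.
* The plate ledger grows with the number of distinct signatures and
  assigned molecules; it is in-memory state, suitable for runs of
  (hundreds of) thousands of molecules, not a database.
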