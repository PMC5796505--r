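---
title: "Methods: parsimony tree search and the resampled-score bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony tree search and the resampled-score bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsboot)
```

## The model

Maximum parsimony (MP) scores an unrooted binary topology $T$ for an
alignment by the minimum total cost of character-state changes it requires.
Only *parsimony-informative* sites (at least two states, each in at least
two sequences) can change the ranking of topologies under uniform costs, so
the alignment is first compressed: informative columns are grouped into
distinct site patterns $D_1,\dots,D_k$ with integer frequencies
$d_1,\dots,d_k$ summing to the informative-site count $m$, and

$$MP(T \mid A) \;=\; \sum_{i=1}^{k} MP(T \mid D_i)\, d_i .$$

Per-pattern scores come from the Fitch set algorithm when every
substitution costs 1, and from the Sankoff dynamic program for an arbitrary
symmetric integer step matrix (both are invariant to the internal rooting;
the implementation roots at tip 1).  Three step matrices ship with the
package: uniform; DNA with transitions (A–G, C–T) at cost 1 and
transversions at cost 2; and a protein matrix whose entry for two amino
acids is the minimum number of nucleotide changes between any two of their
codons under the standard genetic code (stop codons excluded), repaired by
Floyd–Warshall shortest-path closure because the raw codon distances
violate the triangle inequality for some triples.  The closure is the
minimal such repair: it is idempotent and never increases an entry.  User
matrices are accepted from a plain-text file; asymmetric matrices and
matrices violating the triangle inequality are rejected rather than
silently repaired.

## The bootstrap approximation

The standard nonparametric bootstrap reruns an independent tree search on
every resampled alignment, which is the dominant cost of an MP analysis.
This package instead searches tree space *once*, on the original alignment,
and evaluates every tree it encounters against all $B$ replicates.  A
replicate is represented by a resampled weight vector
$d^{(b)} = (d^{(b)}_1,\dots,d^{(b)}_k)$, a multinomial draw of $m$ site
slots with probabilities $d_i/m$, and the score of a tree on that replicate
is the exact weighted sum

$$MP(T \mid A^{(b)}) \;=\; \sum_{i=1}^{k} MP(T \mid D_i)\, d^{(b)}_i ,$$

reusing the per-pattern scores already computed on the original alignment.
Unlike the analogous resampled log-likelihood trick for maximum likelihood,
this is not an approximation: the equality is an identity, and the test
suite checks it against from-scratch rescoring.

Two devices cap the cost of offering a tree to all replicates:

* **Score threshold.**  Only trees whose original-alignment total lies
  below a threshold `MP_max` are offered.  `MP_max` starts at $\infty$ and
  after each hill-climbing step is reset to the lower 10%-quantile
  (linearly interpolated, then floored to an integer) of the multiset of
  qualifying totals seen so far.
* **Per-replicate abort.**  Patterns are scanned in descending order of
  their scores on the first tree built in the initial step (ties broken by
  ascending index).  Each pattern has a tree-independent lower bound
  `MP_min`: distinct observed states minus one under uniform costs, the
  minimum-spanning-tree weight on the observed-state cost graph otherwise.
  After pattern $j$, the partial exact sum plus the bound tail is itself a
  lower bound on the replicate score; once it strictly exceeds the
  replicate's incumbent score the scan stops.  The abort changes running
  time only: the differential acceptance test re-runs a whole pipeline with
  aborts off and requires identical replicate trees and scores.

## The search

1. **Initial step.**  100 starting trees by randomized stepwise addition
   (each taxon attached to the score-minimizing edge, ties uniform), each
   followed by best-improvement SPR hill climbing; the trees are sorted by
   score and the first 5 distinct topologies (split-set identity) form the
   candidate set $C$.
2. **Exploration.**  Repeatedly: pick a candidate uniformly; with
   probability 1/2 apply random NNIs to $\lceil 0.5\,(n-3)\rceil$ internal
   edges, otherwise run the parsimony ratchet (add $+1$ weight to a random
   $\lceil m/2 \rceil$ of the $m$ informative site slots, hill-climb under
   the perturbed weights); then hill-climb the perturbed tree under the
   original weights.  Every accepted tree of that climb (including the
   final local optimum) below `MP_max` is offered to the replicates.  A
   step is *successful* when its local optimum scores strictly below the
   candidate-set minimum; a new tree also replaces the worst candidate when
   it is distinct and does not score above the worst.
3. **Stopping.**  The loop ends after $n'$ consecutive unsuccessful steps,
   where $n'$ is the taxon count rounded up to the nearest hundred.
4. **Refinement.**  Each replicate's best tree is hill-climbed under that
   replicate's own weights and replaced on strict improvement.  Supports
   are computed only from refined trees; skipping refinement yields
   over-confident supports.
5. **Summary.**  Each internal edge of the best tree is annotated with the
   percentage of replicate trees containing its split, and a majority-rule
   consensus (splits in more than 50% of replicates) is built.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 1000 | bootstrap replicates; 100 is common for quick analyses |
| `radius` | 6 | SPR radius: max nodes on the path between the original attachment edge and the regraft edge (adjacent edges are at distance 1) |
| `ratchet_fraction` | 0.5 | fraction of informative site slots upweighted by the ratchet |
| `nni_fraction` | 0.5 | fraction of internal edges rearranged by the NNI perturbation |
| `starts`, `keep` | 100, 5 | initial-step searches and candidate-set size |

The defaults for radius and the ratchet follow the tool this method is
modelled on, which found radius 6 and a 50% ratchet the best
score/run-time balance on real data; the 10th percentile for `MP_max`
likewise.  Smaller radii trade score quality for speed.

## Design choices where the method description is open

* **Perturbation mixing.**  "NNI or ratchet" is interpreted as a fair coin
  flip per iteration.
* **Ratchet form.**  "Duplicate 50% of the informative sites" is read as
  the classic weight ratchet: sample $\lceil m/2 \rceil$ site slots
  without replacement (honouring pattern multiplicities) and add $+1$ to
  their patterns' weights.
* **Hill climbing.**  Best-improvement with full neighbourhood
  re-evaluation after every accepted move; ties go to the first move in a
  fixed enumeration order, making climbs deterministic.
* **Trees "encountered" during a climb.**  The accepted intermediates plus
  the final local optimum — not every evaluated neighbour, which would make
  replicate evaluation dominate the run time and defeat the thresholding.
* **Candidate replacement.**  The worst candidate (largest total, oldest on
  ties) is replaced.
* **Score multiset $S$.**  Starts empty at the first exploration step (the
  initial step's 100 climbs are not included) and is capped at $10^5$
  entries by reservoir sampling; the quantile of MP totals stabilizes long
  before the cap matters.
* **Resampling domain.**  Replicate weights resample informative patterns
  only.  Non-informative sites shift every topology's score by the same
  per-replicate constant under uniform costs, so supports are unaffected;
  under non-uniform costs this is an approximation shared with the
  pattern-compression step itself.
* **First tree.**  The pattern evaluation order derives from the first
  stepwise-addition tree (the first tree that exists in a run).

## Numerical conventions

Costs, per-pattern scores and bounds are integers throughout; weighted
totals are exact in double precision (far below $2^{53}$).  The Sankoff
"infinity" is a sentinel of $10^8$, larger than any achievable score and
safe against 32-bit overflow because internal-node vectors never inherit
it.  Support percentages are kept as exact rationals internally and
rounded half-up to integers only in Newick output.  All randomness —
replicate weights, insertion orders, tie breaks (drawn inside the C++
kernels through R's own generator), perturbation choices — flows from R's
single RNG stream, so a master seed makes whole runs bit-reproducible.

## What the synthetic generator does and does not establish

Test fixtures evolve sites independently along a uniform random topology
with a fixed per-edge substitution probability, with uniform exchange
between states.  Pipeline-level checks use a moderate-signal regime
(8–10 taxa, 200–400 sites, probability 0.08, roughly 25–40% informative
sites); the support-calibration check deliberately uses an
information-poor regime (8 taxa, 100 sites, probability 0.03) because
with plentiful signal every inferred branch is true and an accuracy
function over false branches would be undefined.
This validates the machinery: exact scoring, bound validity, search
optimality at exhaustively enumerable sizes, abort neutrality, refinement
monotonicity, and the qualitative behaviour of supports (true branches
scoring higher than false ones, binned support accuracy non-decreasing
above 70%).  It does not emulate rate heterogeneity, gap patterns,
compositional bias or rogue taxa, so green tests say nothing quantitative
about support calibration on real data.

## Known limitations

* No branch lengths; trees are purely topological.
* Scoring is per-tree-visit; no incremental rescoring across SPR moves and
  no bit-parallel vectorization, so large alignments are slow compared to
  optimized C tools.
* TBR rearrangements, parsimony jackknife, multiple equally parsimonious
  trees per replicate and asymmetric step matrices are out of scope.
* Site resampling ignores non-informative sites (see above).

## A small worked run

```{r example, eval = FALSE}
set.seed(1)
sim <- evolve_alignment(n = 8, sites = 300, subst_prob = 0.08)
res <- mp_bootstrap(sim$alignment, cost = "uniform", B = 100, seed = 1)
res
write_mp_boot(res, tempfile())
```
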