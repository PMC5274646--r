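---
title: "Adaptive-seed protein search: models, statistics and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-seed protein search: models, statistics and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Remote protein homologs — sequences sharing a superfamily but often under
20% identity — are what database search tools are really for. Rigorous
Smith–Waterman search (the SSEARCH approach) is the sensitivity reference
but costs O(mn) per pair. Seed-and-extend heuristics trade sensitivity for
speed, and the size of that trade depends on how seeds are chosen. Fixed
length-k seeds (the BLAST approach) treat a seed in a low-complexity,
high-frequency word the same as one in a rare word. Adaptive seeding
instead fixes the *frequency*: at every query position the seed is the
shortest exact match whose occurrence count in the library is at most a
rareness limit *m*. Common words grow until they are rare enough; rare
words stay short. The single parameter *m* is then a direct dial between
speed (small *m*, few extensions) and sensitivity (large *m*, approaching
exhaustive comparison).

`seedaln` implements this engine end to end: a suffix-array index, adaptive
seeding, gapless and gapped X-drop extension under any substitution matrix
with affine gaps, E-values calibrated for arbitrary scoring schemes, the
rigorous Smith–Waterman baseline, and the evaluation methodology used for
remote-homology benchmarks (weighted ROC with an FDR cut-off, per-query
ROC~n~, and alignment sensitivity/precision curves against reference
alignments).

## Scoring model

Alignments are scored by a symmetric integer substitution matrix (BLOSUM62
is bundled in NCBI matrix format; others, e.g. MIQS, can be registered from
a file) plus affine gap costs. A gap of length $L$ costs
$\mathrm{open} + \mathrm{extend}\,(L-1)$: the first gapped residue is
charged `open`. This convention matters — the same "11/1" penalties mean
different things under different conventions — so it is fixed here once and
used identically in the heuristic extension, the Smith–Waterman baseline,
and the score-recompute invariant. Penalties are stored as positive
magnitudes; tools that print them as negative numbers ("−13, −2") are
describing the same costs.

Default gap costs are 11/1 for BLOSUM62 and 13/2 when the MIQS matrix is
selected by name, matching the defaults the matrices are normally run with.

Letters outside the matrix alphabet are scored through the matrix's X
column, or −1 against everything if the matrix has no X row. `*` and `.`
in input sequences are mapped to X at read time with a warning. A matrix
must be *admissible* for local alignment — negative expected score under
the background composition and at least one positive score. This is
enforced when a matrix meets a background-frequency vector (λ computation,
calibration, search), not at parse time: a parsed matrix by itself carries
no composition, and toy matrices that are only marginal under one
composition can be perfectly usable under another.

## E-value statistics

For ungapped local alignment, Karlin–Altschul theory gives the score scale
analytically: λ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$, solved here by bracketed
root-finding to a residual below $10^{-10}$. For gapped scoring schemes no
closed form exists, so `calibrate_gapped()` estimates the Gumbel parameters
by direct Monte Carlo: it aligns `n_pairs` i.i.d. random sequence pairs of
length `seq_len` drawn from the background composition and fits the maximum
score distribution by the method of moments,
$\hat\lambda = \pi / (\hat\sigma \sqrt 6)$, with $K$ recovered from the
location parameter via $\mu = \ln(K m n)/\lambda$. The method-of-moments
fit was chosen over maximum likelihood because it is deterministic, has no
convergence failures, and is accurate at the 1–3% level at the simulation
sizes used — adequate, since E-values are used as ranking thresholds, not
as calibrated probabilities. The fit is deterministic given the seed.

E-values are the raw $E = K\,m\,n\,e^{-\lambda S}$ with $m$ the query
length and $n$ the total library residues; no finite-size ("edge")
correction is applied. This is the simplest defensible choice and is a
deliberate divergence from BLAST-style corrected lengths; because the
calibration itself is performed at finite lengths, the finite-size effect
is partly absorbed into $\hat K$.

Two numerical points about the calibration are worth stating. First, the
fitted λ carries a small positive finite-length bias that shrinks with
`seq_len`; at `seq_len = 200` it is about 2–3% for BLOSUM62, at
`seq_len = 600` under 2%. The ungapped-limit recovery check therefore runs
at `seq_len = 600`, `n_pairs = 2000`, where bias plus Monte-Carlo noise sit
comfortably inside its 5% tolerance. Second, default background
frequencies are the Robinson–Robinson composition (bundled as a text
fixture, overridable per run; a uniform composition is available via
`uniform_freqs()`).

## The search pipeline

The library is concatenated with unique terminators and indexed by a plain
suffix sort — O(n log n) comparisons at desk scale; the index contract is
only the ordering invariant, so a faster construction could be substituted
freely. Seeds never cross sequence boundaries because terminators are
unique and excluded from seeding.

Per query, the pipeline is:

1. **Adaptive seeding.** At each query position (stride 1), the suffix-array
   interval is narrowed letter by letter until the match count drops to
   ≤ *m* (and length ≥ `min_seed_len`); one seed per library occurrence.
   If the count never reaches *m* within the query, the position emits no
   seed — the strict reading of the frequency rule.
2. **Gapless segmentation.** Seeded diagonals are scanned once each with a
   positive-run (Kadane-style) decomposition; a run that contains at least
   one seed and scores at least `gapless_min` becomes a candidate, anchored
   at its best-scoring column. The scan is deliberately *seed-independent*:
   the candidate set for a diagonal depends only on which diagonals are
   seeded, never on seed spans. Because seed sets grow monotonically with
   *m* (a shorter seed at the same position matches a superset of
   occurrences), candidate sets — and hence detected (query, target) pairs
   — are nested across increasing *m*. An earlier design that skipped
   seeds covered by previously computed alignments was abandoned exactly
   because it broke this monotonicity and could park a pair on a
   suboptimal alignment; with one candidate per diagonal run, the extra
   extensions are affordable and the result depends only on the pair's own
   candidate set.
3. **Gapped X-drop extension.** Each candidate anchor is extended outward
   in both directions by affine-gap dynamic programming, pruning cells
   whose best state falls more than `gapped_xdrop` below the running best.
   The best-scoring alignment per (query, target) pair is kept.
4. **Reporting.** E-values are attached, hits below `score_min` or above
   `evalue_max` are dropped, and hits are sorted by E-value ascending with
   deterministic tie-breaking (score descending, then ids); identical
   inputs give byte-identical hit files.

Defaults: `m = 10`, `min_seed_len = 1` (the most sensitive minimum, since
the frequency rule itself controls seed length), `gapless_min = 25`
(roughly 12.5 bits: random 300-residue pairs reach ~30 occasionally, so
this threshold is sensitivity-biased and lets most borderline pairs through
to gapped extension), `gapped_xdrop = open + 30·extend`, `evalue_max = 10`.
The standalone `gapless_extend()` operation keeps the classical
seed-anchored X-drop semantics (default X-drop 10× the maximum matrix
score) for direct use and testing; the pipeline's segmentation scan is its
seed-independent equivalent. These thresholds are the package's own
defaults and are recorded in the hit-file header.

With *m* set very large the engine approaches exhaustive comparison: every
diagonal of every pair is scanned, which is the same asymptotic work as
full dynamic programming. That is expected — adaptive seeding buys its
speed at realistic *m* on large libraries, and the large-*m* regime exists
here to verify completeness against the rigorous baseline, not to be fast.

The Smith–Waterman baseline (`smith_waterman()`, `sw_search()`) is a full
three-state Gotoh DP with the same gap convention, one optimal path
returned, and traceback ties broken in the fixed order match > delete >
insert, earliest coordinates first (local alignments never end in a gap).
When queries and library are the same collection, scores are computed once
per unordered pair and mirrored; the mirrored path is the transposed
traceback, which remains a valid optimal path.

## Benchmark methodology

Homology detection is evaluated at the superfamily level: a hit is a true
positive if query and target share a superfamily, a false positive if they
come from different folds, and *neither* if they share a fold but not a
superfamily (same-fold pairs may be distant homologs, so they are kept out
of both counts). Self-hits are ignored. An optional exclusion-pair file
(fold- or superfamily-level tokens) demotes listed cross-fold pairs from FP
to excluded, mirroring rule sets that remove putatively homologous
cross-fold relations; the rules are consumed from a file rather than
embedded, since they are curated externally.

To keep large superfamilies from dominating, each query's TP and FP counts
are weighted by 1/(number of *other* library members of its superfamily);
queries with no other member are dropped entirely. The weighted ROC curve
accumulates these weights in E-value order (ties accumulate together), and
detection performance is summarised as the largest weighted TP count at
weighted FDR = wFP/(wFP+wTP) ≤ 10%. The FDR formula is the standard
reading of those ROC axes.

Per-query ranking quality uses
$\mathrm{ROC}_n = \frac{1}{nT}\sum_{i=1}^{n} t_i$, with $t_i$ the TP count
before the $i$-th FP and $T$ the query's TP count; when fewer than $n$ FPs
are retrieved, the missing ones each contribute the full observed TP count
(unretrieved hits are treated as FPs). Two conventions here are not
universally standardised and are fixed as follows: queries eligible for the
mean are those with a defined weight, and a query with no retrieved TP
within the FDR cutoff scores 0 rather than being dropped (dropping would
inflate the mean); hits tied in E-value are ranked pessimistically, FPs
first. Same-fold (neither) hits are removed before ranking, consistent
with their exclusion from both counts.

Alignment quality compares each predicted alignment's residue-pair set $N$
with a reference set $S$: sensitivity $|N\cap S|/|S|$, precision
$|N\cap S|/|N|$ (an empty prediction has precision 1 — it contains no
wrong pair — and sensitivity 0). The quality curve sweeps E-value
thresholds and accumulates Σ sensitivity against Σ (1−precision).

## The synthetic benchmark

Real remote-homology benchmarks are built from structural classifications
and structure-based reference alignments; those are external, curated
resources. The generator in this package reproduces their *statistical
shape* so the whole pipeline is testable from scratch: families of remote
homologs with controlled pairwise identity, singleton decoys, and exact
reference alignments.

Each family draws an ancestor from the background composition and evolves
members independently: substitutions at a per-column rate with replacements
drawn from the background excluding the original residue (so identity over
matched columns is exact in expectation), and indel events at `indel_rate`
per site (default 0.02, a realistic order for diverged proteins), split
evenly between insertions and deletions with geometric lengths of mean 2 —
simple and standard choices where no canonical value exists. A family's
`target_identity` is the expected *pairwise* identity between members,
since that is what detection difficulty depends on; the per-branch
identity $b$ is obtained by solving $b^2 + (1-b)^2\bar c = t$, where
$\bar c$ is the chance that two independent substitutions of the same
residue coincide (~0.06 under the default composition). True residue-pair
alignments are composed through the ancestor — positions surviving in both
members and mapped to the same ancestor column — which gives exact ground
truth where a real benchmark would use structural alignments. All
randomness flows from one seed through derived per-family streams.

What the generator does *not* emulate: real phylogenies (members are a
star around the ancestor), position-specific conservation, domain
architecture, low-complexity and repeat regions, and the compositional
quirks of real superfamilies. Passing the recovery floors here shows the
machinery is correct and complete on idealised remote homologs; it does
not certify sensitivity on real twilight-zone proteins, where
position-specific scoring is known to matter.

Study conditions used by the acceptance checks (chosen once as a
desk-scale analogue of a remote-homology benchmark): 20 families × 5
members at pairwise identities 0.35–0.60, ancestor length 300, 500
decoys (~180k residues); a smaller 10 × 3 benchmark at length 150 with 50
decoys for the completeness checks; Gumbel calibration at 1000 pairs of
the matching length.

## Known limitations

* The suffix sort is comparison-based; libraries far beyond desk scale
  would want a linear-time construction and a compressed index.
* One-hit seeding at stride 1 only; no spaced or subset seeds, no repeat
  masking, no translated search, no multi-volume databases.
* E-values have no composition adjustment or edge correction; scores are
  raw matrix units (no bit-score reporting).
* Only one optimal path is reported per pair; co-optimal alignments are
  not enumerated.
* `mean ROC_n` tie handling is pessimistic by design; optimistic ordering
  would report slightly higher values on heavily tied rankings.
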