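---
title: "seedwave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedwave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedwave)
```

seedwave is a desk-scale long-read DNA aligner built from four layers that
are each useful on their own: affine-gap Smith–Waterman local alignment
with a serial and a wavefront matrix fill; FM-index text indexes in which
the reference prefix trie exists implicitly as suffix-array intervals; a
seeding dynamic programme over the query's prefix DAWG crossed with that
implicit trie; and a small map-reduce engine that chunks the reference,
aligns in parallel map tasks and reduces the intermediate records to a
nonredundant set, with per-worker makespan accounting. This vignette
explains the model behind each layer, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

## Local alignment model

Two sequences `q0` (rows) and `q1` (columns) are compared with the local
affine-gap model. The similarity matrix `Z` has its first row and column
fixed at zero and every cell floored at zero; two companion matrices `I`
and `J` track alignments currently inside a gap that consumes only `q1`
or only `q0` respectively:

* `I[a,b] = max(I[a,b-1] - G_E, Z[a,b-1] - G_F)`
* `J[a,b] = max(J[a-1,b] - G_E, Z[a-1,b] - G_F)`
* `Z[a,b] = max(0, I[a,b], J[a,b], Z[a-1,b-1] + R(a,b))`

`R(a,b)` is the match reward for equal symbols and the mismatch penalty
otherwise. A gap of length `k` therefore costs `G_F + (k-1) G_E`: the
first gapped column pays the opening price `G_F` and each further column
pays `G_E`. Note this differs from the other common bookkeeping in which
a length-`k` gap costs `open + k*extend`; the two parameterisations are
interchangeable by a constant shift (`open' = G_F - G_E`), and seedwave
uses the `G_F`/`G_E` form everywhere — including the seeding DP — so that
seeding scores and extension scores are directly comparable.

The boundary rows of `I` and `J` are held at a large negative surrogate
(an impossible state) so they can never win the max; this is a
convention, not a parameter, and any value below `-(max score)` yields
identical matrices.

Backtracking starts at the maximum of `Z` (the smallest `(row, column)`
cell in row-major order among ties) and walks to a zero cell. Ties are
broken deterministically: diagonal over vertical over horizontal, and
within a gap, closing the gap over extending it. Determinism here is a
correctness feature: it makes run-to-run and worker-to-worker outputs
bit-comparable.

`N` is scored as a mismatch even against another `N` by default
(`sw_scheme(special_n = TRUE)`), because in DNA data `N` means "unknown",
and rewarding `N == N` would let runs of unknown sequence masquerade as
alignments. Setting `special_n = FALSE` treats `N` as an ordinary letter,
which is what the classic worked examples on strings such as `"BANANA"`
want. Internally the fills replace `N` by a per-sequence sentinel byte
before the matrix loop, so the hot loop is a plain byte comparison.

### Wavefront fill

Cells on one anti-diagonal of `Z` depend only on the two preceding
anti-diagonals, so they are mutually independent and can be computed in
any order — that independence is the whole point of the wavefront
schedule. `sw_fill_wavefront()` deals the cells of each anti-diagonal to
`lanes` contiguous blocks and processes the blocks in order. Two
implementation notes:

* Bands of 256 consecutive anti-diagonals share one ascending row sweep.
  Within a band, row `a` contributes a short contiguous run of columns,
  and every cell is still computed strictly after its left, upper and
  diagonal neighbours. The banding exists purely for memory locality: a
  literal one-whole-diagonal-at-a-time walk over row-major matrices
  touches one cache line per row per diagonal and is several times
  slower than the serial fill at the 2,000 x 2,000 scale, which would
  misrepresent an approach whose appeal is that it parallelises without
  changing results.
* Lane blocks run one after another on a single core. The package makes
  no thread-level claims; `lanes` is a deterministic scheduling
  decomposition whose output is bit-identical to the serial fill for
  every lane count, and the test-suite holds it to exactly that.

## Text indexes

The reference chunk is indexed as a sentinel-terminated text over
`'$' + 'A'..'Z'` with `'$'` collating below every letter (the DNA subset
`A/C/G/N/T` in real use; the full letter range keeps the textbook
examples such as `"BANANA$"` runnable). The suffix array is built by
prefix doubling — the construction algorithm is deliberately
unconstrained and is verified against a naive sort-of-suffixes oracle —
and the FM-index stores the Burrows–Wheeler transform, cumulative symbol
counts and a full per-position occurrence table (no sampling or
compression; at the 100 kb chunk scale the plain table costs a few
megabytes and keeps backward extension branch-free).

The prefix trie of the reference is never materialised. A trie node *is*
a suffix-array interval, the root is `[0, n)`, and descending to a child
is one backward extension, which prepends a symbol to the represented
string. `locate()` maps an interval back to text positions through the
suffix array.

The prefix DAWG of the query is the collapse of the query's prefix trie:
nodes with identical suffix-array intervals — equivalently, identical
sets of substring start positions — become one class. Because trie
navigation prepends symbols, the DAWG is structurally the suffix
automaton of the reversed query, which gives the 2|Q| node bound, and
acceptance of a string consumes it right to left. Each node carries its
class's start-position set (materialised on demand from the suffix-link
tree) and its interval in the query's own index.

## Seeding dynamic programme

Seeding evaluates states `(a, b)` where `a` is a DAWG node of the query
and `b` a trie interval of the reference. Each state holds three scores:
`E` for paths ending in a symbol-on-symbol step, and `F`/`K` for paths
ending in a gap along the query or the reference. DAWG nodes are visited
in reverse postorder (every parent before every child); trie nodes are
expanded lazily by backward extension from retained states, so only
reference substrings reachable with a positive score are ever touched.
The recurrences mirror the matrix model exactly — `F` and `K` charge
`G_F` to open and `G_E` to extend, and `E` is the maximum of the diagonal
candidate, `F` and `K` — and a state is kept only when `E > 0` (dropped
to the impossible value otherwise). With the heuristics disabled the best
`E` over all states provably equals the best local Smith–Waterman score
between the query and the reference chunk, and the suite checks that
equality on random instances.

A *seed interval pair* is recorded at any state with
`E >= min_seed_score` whose interval is at most `max_interval_width`
wide; `seeds_from_pairs()` expands a pair into one candidate seed per
(reference position from `locate()`) x (query start position of the DAWG
class), deduplicated on `(q_pos, r_pos)`.

Thresholds, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `max_interval_width` | 3 | max occurrences of the matched reference substring |
| `min_seed_score` | 20 | min seeding score `E` (score units; 20 bases' worth of matches at the default `+1`) |
| `extension_window` | 100 bp | flank length of the extension window |
| `min_report_score` | 30 | min score of a reported record |
| `seed_x_drop` | 16 | X-drop pruning of seeding states (score units) |

Two of these deserve their rationale spelled out. `min_seed_score = 20`
demands an anchor worth about twenty matched bases: in a desk-scale
reference a 20-base chance anchor is essentially absent
(`0.25^20 ~ 10^-12` per position pair), while at the simulator's 2%
substitution rate a 1 kb read still contains on the order of a dozen
edit-free stretches of 20+ bases, so real loci are found many times over.
A threshold near one match, by contrast, turns every ~7-base chance
match into a seed and floods the extension stage with thousands of
windows per read. `seed_x_drop` bounds how far a seeding state's score
may fall below a perfect match of the same query depth; it is the
standard X-drop idea applied to the seeding DP, where the paths worth
keeping are near-exact anchors (the extension stage, not the seeding
stage, is responsible for aligning through diverged regions). Both
heuristics — and the interval-width cap — are disabled (`Inf`,
`1e-9`, `Inf`) wherever the suite asserts exactness.

Extension runs full local Smith–Waterman on a window of
`extension_window` bases flanking the seed on both sequences. If the
resulting alignment runs into a window edge that is not a chunk
boundary, the window was too small: it is doubled and the extension
re-run, so reported records are never truncated by the window itself.
Collinear seeds are clustered before extension (same diagonal, and then
diagonals within a 32-position band, with query spans within one
window): a long shared substring yields a qualifying seed at every depth
along one diagonal, and indels shift the diagonals of consecutive
anchors of one locus by a few positions, so extending every one of them
would redo identical work.

## Map-reduce engine

`split_reference()` cuts the reference into chunks of `chunk_len`
(default 100,000 bp) with `overlap` shared positions (default 10,000 bp)
between neighbours; chunk `i` starts at `i (chunk_len - overlap)` and
the last chunk ends at the reference end. Any alignment no longer than
the overlap lies wholly inside at least one chunk, which is what makes
chunked and unchunked runs agree; the overlap should comfortably exceed
the longest alignment expected (reads here are 1,000 bp against a
10,000 bp overlap). Queries can be chunked by the same rule but are not
by default: the convention for query-chunk overlap is not forced by
anything, and splitting a query without overlap can cut true alignments
in two.

A map task takes one reference chunk and all query records, runs the
seed-and-extend alignment for each (the inner loop spreads over `p`
cores), and emits records keyed by `(query id, chunk id)` with
coordinates already translated to global frames. Records whose reference
interval was truncated by the chunk edge are emitted as-is: the
neighbouring chunk finds the full-length version and the reduce rule
removes the fragment, because the fragment overlaps its full-length
version almost entirely.

Shuffle groups records by query id and sorts each group by
`(reference start, -score, chunk id)` — a total, permutation-invariant
ordering. Reduce first collapses exact duplicates (the same alignment
found from two overlapping chunks), then sweeps candidates greedily in
score-then-position order, retaining a record unless it overlaps an
already-retained record of the same query and strand by more than
`redundancy_fraction` (default 0.5) of the shorter interval. "More than
half of the shorter record" is a deterministic, testable reading of
"nonredundant and nonoverlapping": exact duplicates and near-duplicates
vanish, while genuinely split alignments (two loci, or one locus hit on
both strands) survive. The greedy sweep is verified against an
exhaustive fixpoint enumeration on small groups in the test-suite.

Workers are processes on one machine standing in for cluster nodes: `w`
map workers take chunks round-robin, `w` reduce workers take query
groups round-robin, and `p` is the core count per worker. Every
scheduling choice is output-invariant, and the suite pins the final
record set to be identical across `w` in {1, 2, 4}, across chunked vs
unchunked runs, and with the phase overlap on or off. Intermediate
records normally stay in memory; a `spill_dir` writes them as per-task
JSON-lines files instead, standing in for intermediate storage in a
distributed deployment.

### Makespan accounting and phase overlap

Each map worker's makespan decomposes into data fetch, query split,
alignment and store; each reduce worker's into fetch/shuffle-sort,
reduce function and store. The phase aggregates are means over the `w`
workers, and the total is their sum; the cluster-provisioning term of
the full decomposition is identically zero here, since there is no
cluster to provision at desk scale. A worker's measured makespan may
exceed the sum of its recorded components (scheduling overhead), never
the reverse, and the suite asserts exactly that.

With one map task per reference chunk, a query's group is complete only
when the last map task has finished, so "reduce starts when the first
map worker completes" can overlap only the shuffle-insertion work, not
the final aggregation. The engine implements phase overlap exactly that
way: the report's `reduce_start` is the first map-worker completion when
overlap is on and the last when it is off, and the record output is
provably unaffected — a property the suite checks rather than assumes.

## Synthetic data

`generate_reference()` draws i.i.d. bases at a target GC fraction.
`sample_reads()` copies uniformly-placed slices and applies independent
per-base substitutions (always to a different base) and per-position
insertions/deletions with geometric lengths of mean 2, reverse-
complementing half the reads; every read carries an exact edit script
from which it can be re-derived, and the suite checks that round trip.
The default study conditions — 50 kb reference, 100 reads of 1,000 bp,
2% substitutions, 0.5% indels, both strands — are what
`scripts/acceptance.R` runs, and the recovery criterion is a final
record whose implied read origin lies within ±20 bp of the true start on
the true strand.

What this model emulates is coverage-style resequencing noise; what it
does not emulate is everything that makes real long reads hard:
platform-specific homopolymer errors, chimeras, repeats and low-
complexity sequence, structural variation, and base-quality information
(which no part of the scoring uses). Passing the recovery test therefore
demonstrates that the seed-and-extend machinery, the chunking algebra
and the reduce rule are correct and coherent — not that the aligner is
competitive on real instrument data.

## Numerical and degenerate-input conventions

* All coordinates are 0-based, half-open internally; conversion to
  1-based happens only in SAM output (`POS`, with soft clips for
  unaligned read ends and `FLAG` 16 for the reverse strand).
* Scores are integers throughout; there is no floating-point tolerance
  anywhere in the alignment path.
* Empty sequences are legal in the matrix fills (all-zero `Z`, best
  score 0, empty alignment); empty queries are an error for the DAWG,
  which has no empty-substring class to represent.
* A best score of zero backtracks to an empty alignment with zero-length
  intervals rather than an error.
* Reverse-strand records keep query coordinates in the original read
  frame; `ops` always runs along the reference.
* Timing fields are wall-clock seconds (`Sys.time()`); they are the only
  nondeterministic values the pipeline produces, and they never feed
  back into any decision the aligner makes.

## Problem sizes used by the checks

The test-suite exercises: alignment against an independent
gap-enumeration oracle on thousands of pairs up to length 6 (where
exhaustive enumeration is itself feasible and validates the oracle);
wavefront/serial equality on hundreds of pairs up to length 64 at 1–8
lanes; index structures against naive sorting/counting on random texts
up to 300 bp; seeding-vs-full-alignment equality on queries up to 60 bp
against references up to 200 bp; pipeline invariances on ~2 kb fixtures;
and read recovery at the 50 kb / 100-read study conditions. These sizes
were chosen so each property is checked at the largest scale at which
its oracle is exact and affordable, and so the whole suite runs in
minutes on one core.

## Known limitations

* The seeding DP keeps all positive-score states; there is no bounded
  "z-best" state cap, so adversarial inputs (long low-complexity
  queries with the heuristics disabled) can generate large state sets.
* Memory for the matrices is quadratic; there is no linear-memory
  traceback, no banding in the final alignment, and no SIMD.
* One reference sequence per run; multi-contig references should be
  aligned per contig.
* The redundancy rule is interval-based; it does not attempt split-read
  or chimeric-read interpretation.
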