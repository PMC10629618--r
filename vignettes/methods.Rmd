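---
title: "Methods: sequence matching, masking, clustering and fusion detection in protfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence matching, masking, clustering and fusion detection in protfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protfam)
```

`protfam` chains seven stages of desk-scale genome comparison:
fingerprinting, low-complexity masking, identifier encoding, local
alignment search, Markov clustering, hit-matrix families with
multi-domain detection, and gene-fusion discovery. This vignette is the
package's account of how each stage works, which knobs matter, and
where the design was genuinely open.

## Sequence model and canonicalization

Sequences are protein residue strings over the 20 standard amino acids
plus the tolerated extras `B, Z, J, U, O, X` and a trailing stop `*`.
Canonicalization (`canonicalizeResidues`) uppercases, removes
whitespace, strips exactly one trailing `*`, and rejects internal stops
and empty results. Every analysis stage consumes canonical residues;
file interfaces use 1-based inclusive coordinates (the BLAST tabular
convention) and conversion is confined to the readers and writers so
off-by-one drift has a single boundary to cross.

## Fingerprint matching

The fingerprint of a record is the MD5 digest of the ASCII bytes of its
canonical residue string — nothing else enters the digest, so identity
of fingerprints is (in practice) identity of sequences and the digest
is stable across databases that disagree about headers. MD5's
cryptographic weaknesses are irrelevant here: the digest is an identity
map, not a security primitive, and an adversarial collision is not a
realistic input. Should distinct sequences ever collide,
`fingerprintIndex` reports the collision rather than silently merging
the groups. The trailing stop is stripped *before* digesting; a
collection that retains stops would otherwise fingerprint differently,
which is the one interoperability caveat of this scheme.

## Selective low-complexity masking

The detector asks, for each of the 20 homopolymers: how strongly does
any contiguous stretch of the query resemble a run of that residue?
Formally, with substitution matrix $M$ and query $x_1..x_n$, the local
Smith–Waterman score against an unbounded homopolymer of residue $r$
under *infinite gap penalties* equals

$$\max_{1 \le i \le j \le n} \sum_{k=i}^{j} M(x_k, r) \quad\text{(floor 0)},$$

because no optimal alignment can afford a gap. The implementation is
the vectorized prefix-minimum form of Kadane's maximum-subarray
algorithm (earliest maximal end, then earliest start, for
determinism); the test suite checks it against an exhaustive
enumeration of all segments.

Detection is multi-pass: score all 20 targets, and while the best
segment reaches the threshold, record the region, replace the
offending residue's occurrences inside the span with `X` in a working
copy, and rescore. The working copy lets weaker tracts of other
residue types surface once a dominant tract is removed, while reported
coordinates always refer to the original sequence. Ties between
residue types break alphabetically. Masking is *selective*: only the
region's own residue is replaced; other residues inside the span
survive. Consequences that the suite asserts as invariants: sequence
length is preserved; the unmasked residues are a sub-multiset of the
input; and because `X` scores the fallback value −1 against every
homopolymer, re-running detection on masked output finds nothing at
the same threshold (a fixed point).

Parameters: threshold (integer segment score, default 40), matrix
(BLOSUM62), mask character (`X`). The threshold is the main
sensitivity dial — at 40, a pure run of about 8 residues of a
high-self-score amino acid (Q/Q = 5) triggers detection, as does an
alternating two-residue bias of about twice that length. All three are
configuration, not constants.

## Identifier encoding

CoGenT-style identifiers are `Code-tag-vv-nnnnnn`: a 4-letter species
code with initial capital, a free alphanumeric assembly tag, a 2-digit
collection version starting at 01, and a 6-digit serial starting at
000000 assigned in input order. The full original header is preserved
as the description, so encoding loses nothing and `decodeCogentId` is
an exact inverse on the id. Collections exceeding the serial space
(999,999 records) are rejected loudly rather than wrapped. The species
code is supplied by the user's catalog; `suggestSpeciesCode` offers
the conventional derivation (first three letters of the genus plus the
first letter of the epithet, e.g. *Taeniopygia guttata* → `Taeg`) but
is deliberately only a suggestion, because code collisions across a
large taxonomy are a policy question the catalog owner must decide.

## Local alignment and the internal search

Optimal local alignment with affine gaps is delegated to
`Biostrings::pairwiseAlignment` (a gap of length $L$ costs
`gapOpen + L * gapExtend`; defaults 11/1, the BLASTP convention,
verified against an independent three-state Gotoh dynamic program in
the tests). The packaged matrix is BLOSUM62 extended with a fallback
score of −1 for every pair involving `B, Z, J, U, O, X` or `*`; the
fallback keeps masked (`X`) positions inert and tolerates real-data
ambiguity codes without inventing chemistry for them.

The internal all-vs-all and cross-search drivers exist so the pipeline
is exercisable without external BLAST; they emit the standard
12-column tabular dialect. The `bitscore` column carries the raw
Smith–Waterman score. The `evalue` column carries the monotone
placeholder $10^{-S/10}$ — Karlin–Altschul calibration is out of
scope, so thresholds on internally generated pairs-lists should be
expressed as minimum raw scores. For the pipeline defaults we measured
the null: across ~2,500 alignments of independent uniform-random
80–160-residue sequences the maximum score observed is ≈50, while
planted homologs (90% identity over ≥100 residues) score above 500.
The pipeline's default `min_score = 60` therefore sits an order of
magnitude (in implied E-value) above the random band and far below
genuine signal. Large-scale searching remains the job of BLAST or
DIAMOND via the pairs-list interface.

## Markov clustering

`mclCluster` is a native MCL implementation on the dense column-
stochastic matrix: add self-loops (weight = the vertex's maximum
incident weight, at least 1 — the standard regularization that makes
the flow aperiodic; the choice of self-loop rule was open and this one
keeps well-connected vertices from being dominated by their loop);
column-normalize; then iterate expansion (`M^2`), inflation
(entry-wise power $r$ then column renormalization), and pruning of
entries below `prune` followed by renormalization. Column sums are
asserted to be 1 within 1e-9 after every normalization. Iteration
stops when the largest entry change is below `eps` (1e-6) or at
`max_iter` (100), the latter with a warning and clusters read from the
current state.

Clusters are read from the limit matrix's attractors (rows with
positive diagonal mass): each attractor claims the columns where its
row is positive, and attractor systems sharing a member are merged
into one family — two attractors claiming the same vertex are one
attractor system, which also resolves the numerically-tied-attraction
case by construction. A vertex claimed by no attractor row (possible
only without full convergence) joins the family of its strongest
column entry. Families are numbered from 1 by decreasing size, ties by
smallest member id, so output is deterministic and permutation of the
input edge order cannot change the partition (asserted in the suite).

Defaults: inflation 2.0 (the conventional middle of MCL's useful
1.4–5 range; larger is finer-grained, and the suite asserts the
monotone granularity on a bridge fixture), prune 1e-5, eps 1e-6. The
dense implementation is intended for desk scale (up to a few thousand
vertices); beyond that a sparse representation would be the natural
growth path.

Edge weights: `-log10(evalue)` capped at 200 (the cap also stands in
for `-log10(0)`, keeping the matrix well-posed) or raw bitscore;
directed duplicates collapse to one undirected edge with the larger
weight.

## Hit-matrix families and multi-domain detection

`buildHitMatrix` marks cell $(q, s)$ when some hit $q \to s$ passes
the E-value threshold; the diagonal is axiomatically true and never
validated. Search hit lists are asymmetric in practice, and the
symmetrification step resolves each one-way pair with an explicit
alignment test rather than a blanket union or intersection: score the
real pair, score `shuffles` random permutations of one sequence, and
compute $z = (S - \mu_{null}) / \sigma_{null}$. Significant pairs
($z \ge z_{min}$) become mutual hits (the missing direction was a
false negative); insignificant ones are cleared (the present direction
was a false positive). The per-pair shuffle seed is derived from the
sorted pair of sequences, making the test deterministic,
order-invariant, and therefore idempotent — all three asserted over
random matrix batteries. Defaults `shuffles = 100`, `z_min = 10`: an
identical or clearly homologous pair sits hundreds of null standard
deviations out, a random pair rarely exceeds $z \approx 3$, so 10
leaves a wide margin on both sides while 100 shuffles keep
$\sigma_{null}$ stable.

A protein similar to two proteins that are not similar to each other
violates similarity transitivity; that is the operational definition
of a multi-domain protein here, and every violating neighbour pair is
reported as a witness. Core families are connected components of the
validated matrix restricted to non-multi-domain proteins; each
multi-domain protein is then annotated into every core family holding
one of its neighbours. Excluding multi-domain proteins before taking
components is the load-bearing choice: left in place, one two-domain
protein chains two unrelated families into a single component, which
is precisely the artifact this stage exists to prevent.

## Gene-fusion detection

The fusion question is directional: components are sought in the
query species, composites in the reference. `buildRectMatrix` keeps
the best hit per (component, composite) cell with the hit's span on
the composite (repeat decomposition is deliberately out of scope, so
multiple hits of one component collapse to the best one). A composite
with at least two component hits is a candidate if some component pair
survives two filters: spans on the composite may overlap by at most
`max_overlap` (default 0.1, as a fraction of the shorter span —
nonzero to absorb alignment end wobble, small enough that genuinely
co-located hits are rejected), and the components must not be
homologous to each other under the same shuffle z-test (near-identical
components hitting two places mean an internal repeat, not a fusion).
Components surviving in at least one pair are reported; candidates
allow ≥ 2 components rather than exactly 2, so multi-fusions are
reported in full. Swapping the query and reference roles changes the
question asked, and the suite asserts a planted composite is found
only when it sits in the reference set.

## What the synthetic generator emulates — and what it does not

`makeFixture` draws background sequences uniformly over the 20
standard residues. That is a deliberate null model: under it two
independent sequences are unrelated with overwhelming probability, so
every planted feature (biased tract, family triple at ~90% identity,
fusion trio built as A-segment + 10-residue linker + B-segment) has
exact, machine-readable ground truth. What the generator does *not*
emulate: real amino-acid composition (uniform, not database
frequencies), real length distributions, homology at twilight-zone
identity, repeat families, or naturally occurring compositional bias
outside the implants. Passing tests therefore demonstrate correctness
of the algorithms under controlled conditions and clean separation of
signal from a uniform-random background — not detection power on the
harder distributions of real proteomes, where thresholds would need
calibration against real searches.

Fixture sizes used by the suite and the acceptance script — 500
oracle comparisons per engine, 50 background sequences with 3 planted
fusion trios, 20-vertex planted 4-group partitions, 100-matrix
symmetrification batteries, a 36-record end-to-end demo — were chosen
as the smallest sizes at which every failure mode the suite guards
against (spurious hits, merged families, false fusion calls) has room
to occur.

## Degenerate inputs and numerical conventions

Empty FASTA files, records with empty sequences, non-`>` first lines,
11-column pairs-list rows and non-numeric fields all fail fast with
the offending line or record named. Duplicate FASTA ids warn on read
and fail only in stages that index by id. Local alignment scores have
floor 0 with empty (NA) spans; all-negative position scores give a
zero-score empty homopolymer segment. Reversed subject coordinates are
normalized at parse time. A single-vertex graph is one singleton
family; an empty edge set is an empty graph and an empty family set.
MCL inflation 1 removes the granularity pressure entirely and returns
one family per connected component.

## Known limitations

* E-values from the internal search are placeholders; statistical
  calibration requires an external search engine.
* Dense MCL limits graph size to desk scale.
* Fusion detection reports composite-side spans only and does not
  infer domain boundaries.
* The MD5 protocol detects exact identity only; near-identity matching
  is the alignment stages' job.
* Masking thresholds are expressed in raw segment score, so changing
  the substitution matrix rescales their meaning.
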