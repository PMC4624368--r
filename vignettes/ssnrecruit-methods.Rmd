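---
title: "Methods: similarity-network recruitment of divergent environmental homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-network recruitment of divergent environmental homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ssnrecruit` represents a sequence dataset as an undirected simple graph in
which nodes are sequences and an edge asserts homology supported by a local
alignment. Three filters gate every edge:

* **e-value** below `max_evalue` (default 1e-5);
* **adjusted identity** — percent identity multiplied by the alignment's
  coverage of the *shorter* sequence, capped at 1 — of at least
  `min_adjusted_identity` (default 30%). Rescaling by coverage of the
  shorter sequence makes a short perfect match to a fragment score high
  (the fragment is fully explained) while a short match between two long
  sequences scores low;
* **mutual coverage**: the alignment must span at least
  `min_mutual_coverage` (default 80%) of *both* sequences. This is the
  filter that keeps two multi-domain proteins sharing a single domain from
  being linked, and it is what strands fragments as isolated nodes.

When the two directions of a pair were searched separately, the pair is
judged on the better directional hit (higher bitscore, then lower e-value);
multiple HSPs per pair collapse to the best one.

### Per-domain conductance and nucleus families

For a domain $D$ (Archaea or Bacteria by default) within a connected
component, define

$$\phi_D \;=\; \frac{\#\{\text{edges with exactly one endpoint in } D\}}
                    {\#\{\text{edges with both endpoints in } D\}}$$

counted over the component's edges. Low $\phi_D$ means the domain's members
form a dense, inward-looking group: broadly distributed within the domain,
rarely exchanged out of it. A component is selected as a **nucleus family**
when at least two configured domains have $\phi_D$ strictly below
`conductance_threshold` (default 0.4).

Degenerate denominators need a convention. We use: zero internal edges with
positive external edges gives $\phi_D = \infty$; zero internal and zero
external edges (the domain is absent or edgeless) gives `NaN`. Neither
compares below any threshold, so a single-domain component can never pass —
a domain that contributes no internal edge cannot be a "cohesive group",
and letting 0/0 count as zero would absurdly qualify every single-domain
component through its two absent domains. Eukaryote, MGE and environmental
nodes always count as "outside" for the numerator of either prokaryotic
domain.

### Recruitment and topological classes

Nucleus members are searched against the environmental database under the
e-value cutoff and a per-seed hit cap (default 500) only — deliberately
*without* the identity/coverage edge filter, which is applied later when
the exploratory network is rebuilt (all-against-all, hit cap 5000). The
loose recruitment is what allows indirectly connected sequences into the
dataset; the strict rebuild is what decides which connections count.
Round 2 reuses round-1 recruits as seeds against the same database, so the
set recruited with one round is always a subset of the set recruited with
two.

Classes come from breadth-first distance to the nucleus set in the
exploratory network: distance 1 is `class1`, distance 2 `class2`, anything
farther (including disconnected recruits, e.g. fragments) `distal`.
Adjacency to a nucleus always wins: a node touching both a nucleus and a
class-1 node is class 1.

### Closest published relative (CPR)

Each environmental sequence is scored by the maximum adjusted identity over
its qualifying hits against the published (non-environmental) database,
with the arg-max recorded; ties break by bitscore, then id. A sequence with
no qualifying hit is reported as "no CPR", never as identity 0 — absence of
evidence is kept distinct from evidence of total divergence. Sequences
under `cpr_divergence_cutoff` (default 60%) are "highly divergent":
further from everything published than archaeal and bacterial homologs of
these families typically are from each other.

### Divergent cliques

The subgraph induced on highly divergent environmental nodes (no-CPR nodes
excluded by default, since their divergence is unquantified) is mined for
maximal cliques with a Bron–Kerbosch search with pivoting. Output is
canonical — members sorted, cliques sorted lexicographically — so
enumeration order never leaks into results. All overlapping maximal cliques
are reported; `largest_clique_per_component()` provides the
one-per-component reduction some clique tools apply. The default minimum
clique size is 3: a pair of similar sequences is weak evidence for a
"group of related variants", while a triangle already requires three
mutually consistent relationships. A node-count guard (default 10,000)
aborts enumeration on inputs where the search could be pathological.

Cliques are characterized by:

* **average identity** — the mean over unordered member pairs of identical
  columns over mutually non-gap columns; pairs sharing no column are
  excluded with a warning;
* **conserved-block content** — a deliberately simplified stand-in for
  alignment-trimming heuristics: a column is conserved when it is gap-free
  (up to `max_gap_frac`, default 0) and its majority residue exceeds half
  the rows; only runs of at least `min_block_len` (default 10) consecutive
  conserved columns are retained. A clique is "alignable" when more than
  10 columns survive. We implement exactly these three parameters rather
  than the five-parameter heuristic of the classic trimming tools, because
  only the retained-column count feeds downstream decisions;
* **average ω** — the mean of defined pairwise dN/dS values (below).

### Pairwise dN/dS (NG86)

`ng86_pair()` implements the Nei–Gojobori (1986) counting method:
fractional synonymous/nonsynonymous site counts per codon (each position
contributes syn/3 and nonsyn/3 over its three single-nucleotide mutations,
with mutations to stop codons excluded from the opportunity), difference
counts averaged with equal weight over all minimal substitution paths that
avoid stop codons, Jukes–Cantor correction
$d = -\tfrac34\ln(1 - \tfrac43 p)$, and $\omega = d_N/d_S$. Codon columns
with gaps, ambiguity codes or stop codons in either sequence are skipped,
as are columns whose every minimal path crosses a stop. ω is undefined —
reported as `NA` with a flag, and excluded-with-count from clique averages
— when the pair is identical, when $d_S = 0$, or when either proportion
saturates ($p \ge 3/4$).

NG86 stands in for ML-based pairwise estimators (yn00-style): the protocol
uses ω only to establish purifying selection, for which the counting method
is sufficient; the result object carries a method tag so an alternative
estimator could slot in. One counting subtlety worth knowing: when a codon
takes two synonymous hits (e.g. Arg AGG vs CGC), one of its minimal paths
passes through a different amino acid, so path averaging yields a small
positive $d_N$ even though the protein never changed. "Synonymous-only
evolution implies $d_N = 0$" is therefore exact only in the
one-substitution-per-codon regime, and that is where the test suite asserts
it exactly.

Codon alignments are produced by back-threading coding sequences onto
protein alignments (`backthread_codon_alignment()`): each CDS must be
exactly three times the ungapped protein length after stripping a trailing
stop, and must translate to its protein; violations name the sequence and
first offending residue.

## The synthetic-data generator

The generator exists so that the full pipeline can be exercised against
planted truth. Each replicate emits up to three family types:

* **pass** — an archaeal and a bacterial clade (8 members each, 200
  residues, ~75% within-clade identity) whose members sit at ~22% across
  domains, far below the edge threshold, joined through a single
  MGE-labeled *linker* lineage placed midway between the two domain
  ancestors (~56% to members of both clades). The component is connected,
  each domain keeps 28 internal edges against ~8–9 external ones
  (conductance ≈ 0.3 < 0.4): the planted nucleus signature.
* **fail_unbalanced** — the same construction with only two archaeal
  members: one internal archaeal edge against two external ones
  (conductance 2) sinks the component.
* **fail_single** — one bacterial clade; with no second domain the
  component can never qualify.

Why a linker rather than clades that are mutually above the edge threshold?
If every cross-domain pair carried an edge, external edges would scale as
$|A|\cdot|B|$ against $\binom{|A|}{2}$ internal ones, and conductance
$\approx 2|B|/(|A|-1)$ could not fall below 0.4 for both domains at once —
no family could ever be planted to pass. Detectable inter-domain homology
concentrated in one intermediate lineage is both the geometrically
necessary construction and a biologically sensible picture of a family
whose domains diverged anciently with occasional intermediate forms. The
default linker-to-member identity (56%) is the highest the constraint
algebra allows at 75% within-clade identity while keeping cross-domain
pairs two standard deviations below the edge threshold.

Passing families carry environmental structure: a class-1 clade (5 members,
~72% mutual identity) whose ancestor sits at ~47% to a nucleus member
(CPR band 40–55); a class-2 clade (4 members) attached at ~45% to one
class-1 member, which places it at ~21% to every nucleus sequence — below
the edge threshold, reachable only through class 1; an off-network
published "cousin" at ~39% to the class-2 clade, so class-2 sequences have
a measurable CPR (33–45) without acquiring nucleus edges; and a fragment
(40% of full length) that recruitment finds but the coverage rule strands.
Identity targets are converted to per-branch substitution counts with a
chance-agreement correction ($q = 1/19$ for independently substituted
residues); realized identities land within about ±3 points of target, and
all truth evaluation uses realized values. Configurations whose bands
would contradict the edge threshold (e.g. a class-2 band overlapping it)
are rejected at construction.

Environmental clade members are evolved at the *codon* level: an ancestor
CDS is drawn for the clade ancestor protein (uniform synonymous codon
choice), and each member's CDS accumulates single-nucleotide proposals —
synonymous accepted, nonsynonymous accepted with probability ω (default
0.2), stops rejected — until the translated protein reaches its identity
target. Proteins and CDS are therefore mutually consistent by
construction, and clique-level ω estimates recover the planted value.

What the generator does *not* emulate: indels (alignments of planted clique
members are trivially gap-free and equal-length), empirical substitution
preferences (replacements are uniform over the 19 alternatives; the
identity bands, not residue realism, are the contract), rate heterogeneity
across sites, codon usage bias, chimerism and sequencing error. Passing
tests therefore demonstrate the correctness of the graph machinery,
thresholds, estimators and bookkeeping on data whose difficulty is
controlled — not robustness to alignment ambiguity or real metagenomic
noise. On real data, alignments for clique characterization should come
from an external aligner (aligned FASTA is accepted), and hit tables from
a real search engine can replace the built-in aligner entirely.

## Numerical and design choices

* **Identity threshold boundary.** Edges require adjusted identity
  $\ge 30$ (not $> 30$); the boundary form is configurable.
* **Built-in aligner.** Smith–Waterman with affine gaps via
  `Biostrings::pairwiseAlignment` (BLOSUM62, gap open 11, extend 1).
  Percent identity uses identical columns over aligned columns including
  gaps — BLAST's denominator. The e-value is a Karlin–Altschul-style
  transform $E = Kmn\,e^{-\lambda S}$ with fixed $\lambda = 0.267$,
  $K = 0.041$: rank-consistent for filtering and capping, not calibrated
  against any database size. Analyses that depend on exact e-values should
  supply parsed hit tables.
* **Determinism.** Every ordering is explicit (components numbered by
  smallest member id, hits ranked with full tie-breaks down to
  lexicographic ids, cliques canonicalized), all randomness flows from one
  seed, and a pipeline run is byte-identical across repetitions; the run
  manifest records the config snapshot and output digests.
* **Degenerate inputs.** Empty environmental databases, seedless
  recruitment, a conductance threshold of zero, components with absent
  domains, cliques with no defined ω, and pairs with no shared non-gap
  columns all produce empty-but-valid, flagged outputs rather than errors.
* **Problem sizes.** The test suite runs the generator at its default
  scale (three families, ~47 sequences, 200-residue proteins): 100 seeded
  replicates for nucleus-selection recovery, 8 for exact class recovery,
  200 random ≤12-node graphs against brute-force oracles for conductance
  and clique enumeration, and 100 replicate pairs of 500 codons per ω for
  estimator recovery — sizes at which the planted effects are
  unambiguous and the oracles exhaustive.

## Known limitations

The conductance rule inherits the ambiguity of edge-threshold graphs:
families whose realized cross-domain identities straddle the edge threshold
can split or merge components, which is why recovery is asserted
statistically (≥95% of replicates) rather than universally. CPR is only as
complete as the published set supplied; class-1 sequences by construction
have CPR at least at the edge threshold when the nucleus set is part of
the published database, but not otherwise. The conserved-block filter is a
simplification and will not reproduce the column counts of the classic
trimming tools on gappy alignments. NG86 underestimates ω under strong
transition/transversion bias and does not model codon frequencies; it is
used here to detect purifying selection, not to estimate ω precisely.
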