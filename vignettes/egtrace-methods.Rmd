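---
title: "Methods: cataloguing organellar peptidases and tracing their bacterial origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cataloguing organellar peptidases and tracing their bacterial origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

Nuclear-encoded organelle proteins are imported with an N-terminal
targeting peptide that is cleaved on arrival and degraded. Four metallo-
peptidase families perform this processing — the mitochondrial processing
peptidase (MPP), the stromal processing peptidase (SPP), the presequence
protease (PreP) and the organellar oligo-peptidase (OOP) — and all four
have bacterial homologs. `egtrace` takes a proteome collection with
per-species taxonomy and antimicrobial-peptide (AMP) resistance
annotations and asks three questions:

1. Which proteins are homologs of each family (the **catalog**)?
2. Which bacterial lineages sit closest to the eukaryotic homologs on the
   family gene trees (the **proximity** analysis — candidate endosymbiotic
   donors)?
3. Do AMP-resistant bacteria carry and combine these peptidases
   differently from other bacteria (the **co-occurrence** analysis)?

Because the real-data answer depends on a specific proteome release, the
package ships a synthetic gene-family-evolution generator whose ground
truth exercises every stage; all shipped tests and the acceptance script
run on that generator.

# Homolog cataloguing

The catalog stage mirrors standard iterative homology search. A reference
protein per family seeds a Smith–Waterman search of the proteome
(BLOSUM62, gap open 11 / extend 1); hits need E-value ≤ 1e−5 and ≥ 70 %
query coverage, coverage being measured on the reference, which is the
query. E-values use the Karlin–Altschul approximation
`E = K·m·n·exp(−λS)` with the customary gapped-BLOSUM62 constants
λ = 0.267, K = 0.041, computed per sequence pair. Hits are partitioned by
clade; clusters with fewer than 5 hits are merged into the cluster of
their nearest sister clade (minimum clade-to-clade patristic distance on
the taxonomy tree, ties broken alphabetically) until all clusters reach
the minimum or one remains.

Each cluster yields a position-specific profile: members are aligned onto
a reference member and per-column residue frequencies and a majority-rule
consensus are stored. Two open choices are resolved as follows:

- **Profile anchor: the shortest member.** The scan's job is recall
  (retrieving remote homologs); precision belongs to the composition
  filter downstream. Anchoring on the shortest member models the compact
  core architecture, so a homolog with a subset architecture (e.g. the
  two-domain MPP among three-domain relatives) can still clear the
  coverage threshold. Anchoring on the longest member would silently
  exclude short architectures from candidacy.
- **Profile coverage is measured on the profile,** not the hit, matching
  the scan contract (> 70 % of at least one profile, E ≤ 1e−2).

Candidates are annotated with the motif models (E ≤ 1e−2). Multiple
instances of the same motif are found by greedy mask-and-rescan: the best
hit is recorded, its span masked with `X`, and the search repeated —
equivalent to resolving overlapping same-motif hits by descending score.
The composition filter is multiplicity-aware: SPP requires two M16C
instances. A candidate satisfying several compositions is reported under
every satisfied family with the largest required multiset flagged primary
(alphabetical tie-break); this keeps cross-family placements representable
while giving a single label where one is needed. Extra domains beyond a
family's required multiset are catalogued at the stricter E ≤ 1e−5.

# Gene trees

Family trees are built from the concatenation of per-motif alignments of
the annotated motif instances, in composition order; a motif subset can be
selected (the combined tree of the three M16-like subfamilies uses only
the shared M16 and M16C blocks). Default inference is neighbor joining on
Poisson-corrected p-distances (`d = −log(1 − p)`, saturation capped at
p = 0.95): deterministic, dependency-free, and exact on additive
distances. An external approximate-maximum-likelihood tool can be plugged
in by passing a function as `method`; supports, when present, are carried
as node labels but no threshold is ever applied to them. Trees are
midpoint rooted (the diameter endpoints end up equidistant within 1e−9;
an all-zero-branch-length tree is rooted arbitrarily with a warning).

Published family trees identify each family's subtree visually. For a
reproducible equivalent, `count_misclassified()` defines a family's core
clade as the clade maximizing the F1 score between clade and family leaf
sets (ties toward the smaller clade); family members outside their core
clade are misclassified, and foreign leaves inside it are reported too.

# Proximity to the closest eukaryote

For each bacterium and family, three distances to the closest eukaryotic
homolog: the branch-length sum on the gene tree (`dist_E`), the number of
internal nodes on the path (`dist_T`; cherry partners are 1 apart), and
the log10 E-value of the best local alignment against the eukaryotic
homolog set (`dist_S`; log base only rescales, never reranks). A species
with several homologs contributes its minimum (default; a per-homolog
reduction is available). `dist_S` records below the detectability floor
(E > 1e−3, i.e. random-alignment territory) are missing, and missing
values are excluded per metric, never imputed.

`top_k()` takes the k closest bacterial species per family and metric,
globally per family (ties broken by species id); `pan_top_k()` is the
union across metrics, so its size lies in [k, 3k]. The resistant-vs-other
comparison is a one-sided Wilcoxon rank-sum test (alternative: resistant
distances smaller) with a rank-biserial effect size; the test choice is an
assumption recorded here, and raw p-values are reported without
multiplicity correction so users can correct across clades and pairs as
they see fit.

# Co-occurrence

The presence matrix marks a species as carrying a family iff it has at
least one homolog; species with none stay as all-false rows. Enrichment
between resistant and other bacteria uses the exact conditional
(Fisher-type) test on the 2×2 table (co-occurring? × resistant?),
two-sided by default. Resistance is a genus-level flag: all species of a
flagged genus count as resistant. The default contrast is exclusive
(resistant vs non-resistant); the overall co-occurrence rate is also
reported so the inclusive reading (resistant vs whole clade) can be made
without asserting either as canonical. Degenerate margins give p = 1 and
an undefined odds ratio.

# Logo statistics and the catalytic motif

Per alignment column: residue frequencies over the 20 amino acids among
non-gap symbols (`X` counts as missing), gap fraction, and information
`log2(20) − H` in bits against a uniform background. Residue height is
frequency × information, and stack width is the non-gap fraction, so the
heights per column sum exactly to the information — an identity the tests
assert to 1e−9. The small-sample correction `(20−1)/(2·ln2·n)` is off by
default (it would break the analytic identities) and switchable.

The catalytic zinc-binding motif of the MPP catalytic subunit is H at i,
E at i+3, H at i+4, and an E separated from the second H by 76 residues.
The scanner reports every match; a spacing tolerance (default 0) exists
because alignment-derived sequences can carry small indels near the
motif.

# The synthetic generator

The generator is the package's study system, not a convenience fixture.

**Species tree.** Clades grow as ultrametric Yule subtrees (height 0.3)
grafted monophyletically onto a fixed domain backbone
(Bacteria,(Archaea,Eukaryota)), scaled to unit root-to-tip depth — so
clade and domain monophyly are true by construction and time is
well-defined for transfers. The default plan is 6 bacterial clades of 10
species, 12 eukaryotes, 2 archaea; clades alpha/beta/gamma carry
resistant genera (fractions 0.4/0.2/0.4), applied genus-wise (genera of
~3 species, whole genera flagged until the clade's target fraction is
reached).

**Gene families.** A family starts as one lineage on the stem of its
origin group (default Bacteria — so eukaryotes can only acquire it by
scripted endosymbiotic transfer). Lineages then undergo a Gillespie
process: duplication and loss everywhere, horizontal transfer restricted
to bacteria→bacteria, at default rates 0.1 / 0.05 / 0.05 events per unit
branch length — low enough that family presence is typical but gains and
losses happen. Scripted EGT events name a donor clade and a recipient
stem; the default event time is the midpoint of the window where the
recipient edge overlaps the donor clade's existence, and the donor gene is
drawn uniformly from lineages alive in the donor clade at that time. A
transferred lineage can subsequently go extinct; that outcome stays in
the event log, and analyses conditioning on an EGT-founded eukaryotic
family check the ground truth first.

**Sequences.** A protein is leading linker + domain blocks + trailing
linkers (one fixed random model sequence per motif id; the M16-like model
embeds the catalytic pattern at offset 5, pinned in the MPP family's root
copy). Sites substitute with probability `1 − exp(−r·l·m)` per branch
(`r` = 0.3 substitutions/site per unit branch length by default, i.e.
0.3 expected root-to-tip divergence; `m` = 0.5 inside blocks, 1.5 in
linkers), the replacement drawn uniformly over all 20 amino acids — so the
realized change probability is 19/20 of that. Families' root copies of
shared blocks are pre-diverged from the ancestral model by 0.4
substitutions/site, roughly twice the within-family divergence, so the
M16-like subfamilies are distinct but alignable, as required for the
combined tree to be family-structured. Linker lengths drift (Poisson
around 15 residues) only on branches carrying divergence, producing
alignment gaps; blocks never indel internally, but each block is deleted
wholesale with probability 0.05 per extant gene at the default noise
level, producing true composition-filter negatives with exact truth.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic substitution matrices and
site-heterogeneous rates, indels inside domains, gene conversion,
compositional biases, incomplete or contaminated proteomes, and the
8,000-proteome scale. The generator's role is to verify that each
algorithmic step recovers a planted, knowable signal, not to reproduce
published counts, which are inputs-dependent.

# Numerical choices and problem sizes

Deterministic streams: one root seed, with per-stage and per-family
derived seeds, so adding a family never perturbs another family's draws,
and identical configuration yields byte-identical outputs (asserted by a
test on full pipeline runs). Coordinates are 1-based inclusive. NJ branch
lengths are clamped at 0. Tie-breaks are lexicographic everywhere a rank
is cut (top-k membership, closest-eukaryote choice, consensus residues,
merge targets). Tests run at the default 74-species / 4-family scale
(~250 genes); oracle-equivalence checks use 100–200 random trees of 5–100
leaves, 500 birth–death replicates on a 3-species tree, 1,000 random
sequences for the motif scanner, and full enumeration of 2×2 tables up to
n = 40; donor recovery uses 20 replicate single-family fixtures at
k = 10.

# Known limitations

- The Karlin–Altschul constants are fixed rather than fitted; E-values
  are internally consistent, not calibrated against any external search
  tool.
- Reference-anchored profile alignment discards insertions relative to
  the anchor; a profile HMM would model them.
- The max-F1 core-clade criterion can differ from a visual subtree choice
  when a family is deeply paraphyletic.
- `dist_T` counts nodes on the rooted tree's paths, so the (degree-2)
  root counts as an internal node when the path crosses it.
- The rank-sum and Fisher tests are the package's choices where the
  analysis tradition leaves the test unnamed; both are recorded in the
  output schema.
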