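---
title: "Methods: discovering and classifying RT-associated CRISPR-Cas loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and classifying RT-associated CRISPR-Cas loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcrispr)
```

## The problem

A minority of type III CRISPR-Cas systems carry a reverse transcriptase
(RT) gene near — or fused to — the adaptation module, enabling the
acquisition of spacers from RNA. Characterising these systems requires a
chain of genomic analyses: collecting and dereplicating RT proteins,
finding the CRISPR arrays near them and deciding their transcriptional
orientation, annotating the surrounding *cas* genes, trimming the locus to
its functional extent, classifying the effector complex (Csm vs Cmr) and
the RT fusion architecture, grouping the RTs into phylogenetic clades, and
asking whether the RT and the adjacent Cas1 share an evolutionary history.
`rtcrispr` implements this chain as composable, deterministic functions,
together with a synthetic-data module that plants every signal with a
known truth so each stage can be validated quantitatively without any
external database.

## Sequence comparison and its statistics

All sequence comparison runs on exact affine-gap dynamic programming
(compiled): end-gap-free global alignment for identity, Smith–Waterman for
search. A gap of length $L$ costs $o + L e$ with defaults $o = 11$,
$e = 1$ (the familiar BLAST-style 11/1 accounting) over BLOSUM62.

**Percent identity** is defined as the number of identical aligned
positions divided by the length of the shorter sequence (the CD-HIT
denominator). Among co-optimal alignments the maximum match count is
taken — computed exactly by a second dynamic program — so identity is a
property of the optimal alignment *set*: symmetric, reproducible, and
independent of traceback tie-breaking.

**E-values** follow the extreme-value form
$E = m n \cdot 2^{-S'}$ with $S' = (\lambda S - \ln K)/\ln 2$.
Because the package computes exact optimal local scores over the full
$m \times n$ space (no heuristic seeding, no edge correction), published
asymptotic $(\lambda, K)$ pairs systematically overstate significance
here. The defaults $\lambda = 0.22$, $K = 0.021$ were instead fitted once
to the empirical Gumbel distribution of scores of random 150–600-residue
protein pairs under this exact scoring. This calibration is what makes
two guarantees hold simultaneously: diverged gene copies of a profile hit
it at $E \ll 10^{-6}$, while codon-shuffled decoys essentially never reach
the $E \le 0.01$ annotation threshold (the generator additionally audits
every decoy at generation time). Both parameters remain user-settable in
`search_params()`.

**Dereplication** (`dereplicate()`) drops sequences shorter than 200
residues and greedily keeps, longest-first, every sequence whose identity
to all previously kept representatives is at most 85% — the standard
"unique representatives" reduction applied to RT datasets. Greedy
longest-first was chosen because the procedure it emulates reports only
the end state; the order rule is stated explicitly so it can be oracled.

**Consensus building** (`build_consensus()`) uses a centre-star
progressive alignment (sequences merged into a running profile in
decreasing identity to the longest member) and emits per column the
residue exceeding the majority fraction, else `X`. This is intentionally
simple: it is used on clade members that are at least ~60% identical,
where centre-star alignment is effectively exact; an externally computed
alignment can be supplied instead wherever an alignment is consumed.

## Array detection and orientation

`detect_arrays()` is a k-mer-seeded (k = 8) periodicity detector:
positions sharing an 8-mer at spacings compatible with a repeat of
19–48 bp and a spacer of 17–72 bp seed a candidate, whose repeat unit is
then extended column-by-column while at least 70% of the copies agree.
Candidates must keep every copy within 85% identity of the repeat
consensus and every spacer within the length window; overlapping
candidates resolve to the one with more repeats, then the longer span,
then the leftmost. The detector is exactly mirror-symmetric under reverse
complementation.

Orientation uses two biological signals: the leader flank is AT-richer
than the trailer flank, and the trailer-proximal repeat copy is the most
diverged from the consensus. `score_orientation()` sums the AT-fraction
difference of the 200-nt flanks and the terminal-degeneracy asymmetry
into one signed score (positive = leader left). Absolute scores of at
least 0.12 are band H, at least 0.05 band M, else L; if either flank is
shorter than 200 nt the band is NA regardless. The thresholds are
package-defined (the scoring systems this emulates do not publish
theirs): they were placed so that the generator's strong-signal regime
(leader AT-enrichment ≈ 0.2, three terminal-repeat mutations) lands in H
while zero-signal arrays land in L, with the flank-sampling noise
(sd ≈ 0.05 for 200-nt flanks) spanning one band.

`resolve_orientation()` then applies the three-criterion cascade:
(i) accept the score orientation iff the band is H or M; otherwise
(ii) an exact (or reverse-complement) match of the repeat consensus in an
oriented repeat database fixes the orientation; otherwise (iii) at least
90% identity (either strand) to the repeat of an array already oriented
by (i)/(ii) lets the array inherit that orientation. Arrays exhausting
the cascade stay `undetermined`; criterion-(i) calls are never
downgraded. The 90% criterion-(iii) threshold is package-defined.

## Annotation, trimming, classification

`annotate_cas()` searches every gene translation against the profile set
and keeps the best family at $E \le 0.01$; hits are *subtype-specific*
iff $E \le 10^{-6}$ and the family is a type III signature (csm2–csm5 for
III-A/D, cmr1/cmr3–cmr6 for III-B/C; cas10 is deliberately not
discriminative because both subtype groups carry it).
`classify_subtype()` reports III-A/D or III-B/C from those signatures,
`ambiguous` if both appear, `partial` when cas genes are present without
a signature, `unknown` otherwise.

`detect_fusion()` reads the RT gene's domain architecture: a Cas1 domain
C-terminal to the RT makes it RT-Cas1; an additional Cas6 domain
N-terminal to the RT makes it Cas6-RT-Cas1; otherwise RT alone. Domain
order is compared by midpoints, which is robust to the few-residue
uncertainty of local-alignment domain boundaries.

`extract_locus()` implements the trimming rule: starting from the RT
gene, candidate elements (annotated cas genes and arrays within 50 kb)
are chained greedily left and right while the intervening gap is
*strictly* less than 5 kb, and the region is trimmed to the outermost
retained element. Gaps are counted in intervening nucleotides
(`next_start − prev_end − 1`), so a 4,999-bp gap is retained and a
5,000-bp gap is excluded; the boundary is pinned by tests. The rule is
applied uniformly to genes and arrays (the end state alone does not say
whether it applied only around arrays), and extraction is idempotent.
Whether an array lies within 1 kb of the RT gene is recorded per locus.

## Phylogenetic clades and congruence

`build_tree()` is a desk-scale neighbour-joining implementation with
Poisson-corrected distances ($d = -\ln(1 - p)$ over shared non-gap
columns; pairs with fewer than 10 shared columns are set to the maximum
distance) and bootstrap supports from column resampling. It deliberately
does not re-implement maximum-likelihood inference; externally inferred
support-annotated Newick trees are accepted everywhere a tree is
consumed. Note the calibration caveat: the 0.92 support rule below was
formulated for local (SH-like) supports, which are numerically more
generous than bootstrap frequencies; applying it to bootstrap supports is
conservative, and this difference is documented rather than hidden.

`assign_clades()` turns a support-annotated tree into a partition:
internal nodes with support ≥ 0.92 whose leaves include at least two
CRISPR-associated sequences and *no* non-associated sequence are
candidates, and maximal candidates become clades. The purity constraint
is what bounds clades on trees that mix CRISPR-associated RTs with their
group II intron relatives — without such background lineages any deep,
well-supported node would qualify. `split_subclades()` letters
well-supported children (≥ 3 leaves) in which at least 90% of leaves come
from one phylum, but only inside clades that are phylum-mixed overall;
"many sequences restricted to particular phyla" is operationalised as
purity ≥ 0.9 with minimum size 3 because no numbers are stated for it.

`build_clade_models()` equips each clade with a member consensus, the
e-value window of members against that consensus, and an exclusion
threshold at the log-midpoint between the worst member e-value and the
best non-member e-value — a data-driven analogue of a fixed
"no outsider below e-75" cutoff, which is dataset-specific and therefore
recalibrated per run. `screen_membership()` assigns a query to the
best-e-value model iff it clears that model's threshold; ties are
ambiguous and return `none`.

`test_monophyly()` uses unrooted semantics: a label is monophyletic iff
its leaf set is one side of a bipartition (the label complement acts as
the outgroup). `partition_congruence()` combines the adjusted Rand index
over shared leaves with a per-label surface — for each clade, whether its
leaf set is monophyletic in both trees — which is exactly the comparison
used to argue for or against RT/Cas1 coevolution: congruent clades agree
in both trees, scrambled (polyphyletic) clades fail in the second.

## The synthetic-data module

The generators are first-class, tested code, and their defaults *are* the
study conditions of the test suite:

* **Genomes** (`generate_genome()`): planted loci follow the canonical
  type III architectures (Csm and Cmr effector operons, adaptation module
  at the RT-proximal end, array adjacent to the RT gene) for all three
  fusion classes. Genes are profile copies diverged at 12% substitutions
  — comfortably inside profile-detection range, comfortably outside
  identity-collapse range. Intergenic gaps default to 50–300 bp; a
  template knob plants an oversized gap to exercise the trimming
  boundary. Decoy genes are codon-shuffled and audited against all
  profiles at generation time. A guard stop codon precedes each planted
  gene so ORF calling recovers exact coordinates.
* **Arrays** (`array_spec()`): repeats 19–48 bp, spacers pairwise
  distinct with community-typical lengths (defaults 30–40 bp; no
  repeat/spacer length distributions are published for this setting),
  leader AT-enrichment and trailer-repeat degeneracy parameterised so
  tests can produce H-, M- and NA-band arrays on demand, and an option to
  draw the repeat from the oriented repeat database so the cascade's
  database criterion is testable.
* **Protein families** (`generate_protein_family()`,
  `generate_rt_clades()`): identity ladders hit their targets exactly by
  construction (substitutions at distinct positions) and are verified
  internally against `pairwise_identity()`; the clade-structured variant
  adds non-CRISPR background lineages from the same ancestor, mirroring
  the role of group II intron RTs on real trees.
* **Trees** (`generate_clade_tree()`): planted clades are monophyletic
  with support `support_high` (≥ 0.92); all other nodes get
  `support_low`, so the 0.92 rule recovers exactly the planted partition.

What the generators do *not* emulate — and hence what green tests do not
show about real data: sequencing error, assembly fragmentation, genuinely
degenerate arrays (internal repeat indels), compositional bias shared
between decoys and real genes, phage/plasmid spacer provenance, and the
acquisition biochemistry itself. Results on synthetic genomes bound the
algorithmic behaviour, not the biological error rate.

## Numerical and design choices

* Problem sizes in the shipped tests and the acceptance script — 50
  genomes of 100 kb for detection, 200 arrays for orientation, 50
  proteins for dereplication, 100-leaf trees with 12 clades, 100 random
  12-leaf trees for the monophyly oracle — were chosen as the smallest
  sets at which the measured rates stabilise.
* All generators are pure functions of their spec and seed; the pipeline
  seeds every stochastic step from one configuration seed, and two runs
  with the same configuration are byte-identical on disk (timings are
  logged to memory, not to the reproducible log file).
* Ties: overlapping array candidates resolve by (repeats, span,
  leftmost); equal-best e-values in membership screening are ambiguous by
  design; co-optimal alignments are summarised by their maximum match
  count rather than a traceback choice.
* Degenerate inputs follow explicit contracts: empty target sets give
  empty hit tables, an all-gap or sub-3-sequence alignment is an error,
  an all-equal distance matrix still yields a tree, and detection on
  pathological contigs returns an empty table rather than failing.
* The III-A vs III-D and III-B vs III-C distinctions are not
  operationalised (only the merged labels are used), matching how these
  systems are reported for RT-associated loci.

## Known limitations

The profile set shipped with the package is synthetic (random consensus
sequences paired with the generator); real annotation requires supplying
real profiles through the same interface. The NJ/bootstrap tree builder
is for desk-scale validation, not publication phylogenetics. Criterion
(iii) of the orientation cascade uses the whole oriented set of the run
as the "group" when no clade grouping is available yet. Array family
classification beyond repeat-database matching is out of scope.
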