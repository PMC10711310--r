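---
title: "Methods: pangenome partitioning and phenotype-group signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome partitioning and phenotype-group signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Collections of closely related bacterial genomes — cultured isolates plus
metagenome-assembled genomes (MAGs) — are increasingly used to ask whether
strains recovered from hosts with different clinical outcomes differ
genetically. The motivating setting is vaginal *Lactobacillus jensenii* from
preterm (PTB) versus full-term (FTB) pregnancies: a handful of genomes per
group, pairwise ANI around 99–99.9%, and the question of whether the
PTB-associated strains form their own clade and carry their own genes and
core-gene variants.

`pangsig` implements that comparative workflow end to end, with a synthetic
pangenome generator whose ground truth makes every stage testable as a
parameter-recovery problem. This vignette records the models, the defaults,
the numerical choices, and what the tests do and do not establish.

## Alignment engine

All sequence comparison runs through one affine-gap pairwise aligner
(Gotoh three-state dynamic programming, compiled): global (Needleman–Wunsch)
for clustering and MSA construction, local (Smith–Waterman) for marker
search and ANI fragments. A gap of length $L$ costs
$g_\mathrm{open} + (L-1)\,g_\mathrm{ext}$. Protein defaults mirror BLASTp
(BLOSUM62, $-11/-1$); DNA uses $+1/-1$ with $-5/-2$ and neutral `N`. No
alignment parameters are inherited from the motivating study (none are
published there); all are arguments.

Two choices are fixed project-wide because downstream thresholds depend on
them:

* **Identity** is matches divided by alignment columns, excluding only
  dual-gap columns — a gap column counts *against* identity. Tools differ
  here; fixing one definition makes "95% identity" unambiguous.
* **Traceback ties** prefer diagonal over up (gap in the second sequence)
  over left, and the local aligner takes the first best cell in row-major
  order, so outputs are byte-identical across runs.

Multiple alignment uses the center-star heuristic: the center maximizes the
summed global scores to all other members (ties to the lexicographically
smallest id), others are merged under "once a gap, always a gap". For
intra-species gene families at ≥95% identity the members differ by a few
substitutions and rarely an indel, so the $O(k^2)$ center-star optimum gap
placement is essentially exact; de-gapping any row always reproduces its
input, which the tests assert.

## Gene families and the pangenome

Clustering is greedy and representative-based (CD-HIT-like): proteins sorted
by decreasing length (ties by gene id), each joining the first family whose
representative it matches at identity ≥ 0.95 under global alignment, else
founding a new family. This is a deliberate reimplementation of the
CD-HIT+BLAST+MCL stacks used by pangenome pipelines, chosen because it is
single-pass, deterministic and order-invariant after the stated sort; on
real data its family counts are expected to agree approximately, not
bit-exactly. A conservative shared-5-mer prescreen skips representatives
that provably cannot reach the threshold (a pair at identity $\ge t$ shares
at least $(\min - k + 1) - k(\lceil\frac{1-t}{t}\max\rceil + 1)$ k-mers), so
the prescreen never changes the result, only the cost. Paralogs collapse to
a single presence; a side report lists them.

The presence/absence matrix is partitioned by presence fraction $c/G$:
core at ≥ 0.95, shell at \[0.15, 0.95), cloud below. The rule is
fraction-based with no integer rounding: at $G = 15$, $0.95 \times 15 =
14.25$, so core means all 15 genomes — the "≥95% of strains" convention with
core and soft-core merged.

Openness follows Heaps' law. Random genome orderings (all $G!$ of them when
that is cheaper than the requested permutation count, otherwise sampled)
give a mean rarefaction curve $P(N)$, fitted as $P(N) = \kappa N^\gamma$ by
least squares on $\log P$ vs $\log N$; $\gamma > 0$ (beyond a $10^{-6}$
tolerance) means OPEN. The fit recovers exact power laws to numerical
precision, and simulated infinitely-many-genes regimes ($u$ novel families
per genome) classify OPEN for $u > 0$ and CLOSED for $u = 0$.

## Group association and group-exclusive variants

Association is a pan-GWAS screen: per family that is neither universally
present nor absent among labelled genomes, a 2×2 presence-by-group table is
tested with a two-sided Fisher exact test (sum of hypergeometric
probabilities ≤ the observed table's, ties within relative tolerance
$10^{-7}$), then Bonferroni and Benjamini–Hochberg corrections over the
tested set. The phylogenetically aware pairwise comparisons of pan-GWAS
tools are intentionally out of scope; with a handful of genomes per group
the exact test's resolution floor (here $1/5005$ for 6 vs 9 perfect
separation) is the operative limit, and no significance cutoff is
hard-coded.

The variant scanner looks at per-family core protein alignments whose rows
are genomes. **Strict** mode (default) reports a column when every
target-group row carries one identical residue (no target-side gaps) and
that residue never occurs in the other group — the natural reading of
"mutations specific to" one group, since a fixed residue cannot be asserted
across a gap. **Lenient** mode ignores gapped rows and requires disjoint
residue sets; it is kept because gap policies differ between scripts in the
wild, and both counts are reported. Scanning at the protein level suffices
for "non-synonymous": differing aligned amino acids are non-synonymous by
construction, and no codon back-mapping is attempted.

## Phylogeny

The core-genome tree is distance-based by design: maximum-likelihood
inference is out of scope, and for clade questions at 99%+ ANI the signal is
topological. Strict-core family alignments are concatenated in sorted
family order (with a column-provenance map back to families), distances are
p-distances over pairwise non-gap columns (Jukes–Cantor or Poisson
corrections available; nucleotide JC saturates at $p \ge 0.75$ and errors
rather than extrapolating), and trees come from an in-package
Saitou–Nei/Studier–Keppler neighbor joining with deterministic
smallest-index tie-breaking. Additive matrices are recovered exactly
(tested to $10^{-9}$ on random additive trees); negative branch estimates
are clamped to zero with the deficit moved to the sibling edge so Newick
output is non-negative. Bootstrap supports resample alignment columns with
replacement (default 100 replicates, tunable to the thousands), rebuild the
NJ tree per replicate, and report the percentage of replicates containing
each bipartition of the full-data tree. Internally the replicates are
matrix products over per-pair mismatch/gap incidence restricted to variable
columns, which makes thousands of replicates cheap without changing the
estimator.

## Fragment ANI and the species gate

ANI follows the fragment-mapping recipe: the query is cut into consecutive
1000-bp windows (tails discarded), each window is placed on the reference by
shared 16-mer seeding over exact diagonals in both orientations (more seed
votes wins), locally aligned to the implied reference window (±50 bp
margin), and counted when the alignment spans ≥90% of the fragment at
identity ≥ 0.8. ANI is 100 × the mean identity of counted fragments;
if nothing passes the ANI is *undefined*, never 0. The coverage requirement
is this package's own mapping criterion (the reference tool's internal
cutoffs are unpublished): without it, a fragment seeded by chance could
count through a short perfect local hit. ANI is computed one-way and is
approximately symmetric; the two directions are never averaged silently. A
`max_fragments` knob (evenly spaced subsample) bounds the cost of all-pairs
matrices; the analysis scripts use 30 fragments per pair, which holds the
per-pair standard error near 0.05 ANI points at 99% identity. The species
gate assigns a genome to the reference species with the highest defined ANI
when that ANI meets the conventional 95% boundary, ties to the
lexicographically smallest species name, else UNASSIGNED.

Calibration on synthetic genomes: self-ANI is exactly 100; a 1%
uniformly mutated copy measures 99.0 ± 0.3; unrelated random sequence finds
no seeds and stays undefined; 98%-ANI queries pass the gate and 90%-ANI
queries are rejected.

## Quality gates and marker profiling

MAG quality gating keeps genomes with completeness ≥ 90% and contamination
strictly < 5% (the strict inequality matters at the boundary and is
asserted in tests). Marker profiling mimics a protein BLAST of a gene
cluster against each genome's proteome: candidates share at least two
6-mers with the marker (every gene is tried for very short markers), the
best local alignment by score wins (ties by gene id), and presence requires
identity ≥ 0.7 and ≥ 0.8 coverage *of the marker* — marker-side coverage so
fused or split genes in MAGs still count. The 0.7/0.8 defaults are this
package's own (none are published for the motivating figure), mandatory
arguments, and echoed into the output header for provenance. Per-clade
presence fractions and a concordance score (difference between clades'
fractions) summarize how clade-restricted each marker is.

## The synthetic pangenome generator

The generator is the package's instrument for turning every stage into a
parameter-recovery test. Defaults are the study conditions: 6 + 9 genomes,
500 core families of 300 aa (a desk-scale stand-in for a ~1200-family
core), 14 planted group-1-specific families, 185 planted group-fixed
variants, 0.5% per-site background amino-acid divergence per genome copy
(the ~99.3–99.9% ANI intra-species regime), a 100-family shared accessory at
50% presence plus Poisson(10) genome-private novel families (an open
regime), and no flip noise or MAG degradation unless requested.

Design choices worth recording:

* Planted variants are *protected* from background mutation, so the truth is
  exact rather than probabilistic; 185 variants scattered uniformly over
  500 families land in ~155 distinct families, the same shape as the
  motivating cohort's 185-in-156.
* Proteins are reverse-translated once at the ancestor (uniform synonymous
  codons); per-genome amino-acid changes re-draw only the affected codon.
  Nucleotide divergence therefore tracks amino-acid divergence from below,
  and dedicated ANI tests mutate nucleotides directly instead.
* Gene order, gene strand and intergenic spacers are ancestral — shared
  across genomes, spacers mutated per genome at the background rate — since
  within a 99%-ANI species intergenic DNA is homologous and orientation is
  conserved. Accessory presence differences then look like honest
  insertions/deletions to the ANI machinery.
* MAG degradation drops each gene with probability completeness/100, adds
  contaminating genes copied from a donor genome, reassembles the contig,
  and records the *realized* completeness/contamination in the metadata.
* Everything derives from one seed; the emitted FASTA/GFF3/TSV/JSON files
  are byte-identical across runs with the same seed.

What the generator does *not* emulate — operon structure, GC skew,
recombination, indel processes inside genes, annotation errors — bounds what
green tests mean: they establish that the algorithms recover planted truth
under the stated model, not that real-data counts will match any published
figure exactly. The clustering reimplementation note above applies to all
real-data comparisons.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes QC → clustering → matrix → partition/Heaps →
association → core MSAs → variant scan → NJ+bootstrap → (optional) ANI →
(optional) marker profile, each stage writing fixed-name artifacts and an
MD5-hashed manifest entry; stages communicate only through serialized
artifacts, so any stage can be re-run from files (the `analysis/` scripts do
exactly that). Per-stage seeds derive from the base seed by hashing the
stage name modulo $2^{31}-1$, so adding a stage never perturbs another's
stream.

Problem sizes used by the shipped analyses and tests — the 15-genome,
~8500-gene cohort, 100 rarefaction permutations, 100 bootstrap replicates,
30-fragment ANI subsamples, 50-kb calibration genomes — were chosen so a
single desk run of the whole workflow completes in a few minutes while
keeping every estimate's sampling error well inside the margins the tests
assert.

## Known limitations

* Greedy clustering can split a family whose true diameter straddles the
  threshold (first-founder dependence); at intra-species divergence this
  does not occur, and the planted-recovery tests would catch it.
* Center-star MSA is not optimal for divergent families with complex indel
  structure; it is used only on ≥95%-identity families.
* Fisher association ignores phylogenetic structure; with clonal groups it
  will flag lineage markers as associations, exactly as naive pan-GWAS
  does.
* NJ substitutes for ML: branch lengths are distance estimates and
  support values are column-bootstrap proportions, adequate for clade
  questions, not for rate inference.
* Fragment ANI is seeded (16-mers, both orientations) and windowed; highly
  rearranged references within a fragment length could evade the single
  best diagonal.
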