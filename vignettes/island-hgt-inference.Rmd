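---
title: "Delineating genomic islands and dating their acquisition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating genomic islands and dating their acquisition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

Metabolic traits in bacteria are often carried on *genomic islands*:
chromosomal segments acquired by horizontal gene transfer (HGT), typically
integrated at tRNA genes by site-specific recombinases and bounded by a
short duplicated target site (a pair of flanking direct repeats). Given a
set of closely related genomes — some carrying an island, some not — three
questions recur:

1. **Where exactly is the island?** (boundary delineation)
2. **How does it move?** (tRNA-integrative element, integrative and
   conjugative element, composite transposon)
3. **When and how was it acquired?** A single ancestral acquisition followed
   by vertical descent predicts that island and chromosomal backbone carry
   the *same* divergence between strains; recent independent acquisitions
   predict an island far more conserved than the backbone.

`islescan` implements this chain of inference as composable, tested stages,
plus a forward genome-evolution simulator that provides exact ground truth
for every stage. The simulator is first-class, not a test fixture: its
defaults define the study conditions all properties are checked under.

# Orthology and locus selection

Proteomes are derived by strand-aware translation of annotated CDS features
(internal stop codons, as found in pseudogenes, render as `X` so alignment
still works). Homology is scored by optimal Smith–Waterman local alignment
with affine gaps (BLOSUM62; gap open 11, extension 1; a gap of length $g$
costs $11 + g$). Hits require score ≥ 50 and alignment length ≥ 50% of the
shorter sequence; both thresholds are config-exposed. Identity is defined as
matches / alignment columns of the optimal traceback, gaps counting as
columns.

Orthologs are called by **reciprocal best hits** (RBH): $(a, b)$ is kept iff
$b$ is $a$'s unique best-scoring match in the other genome and vice versa;
ties for best are treated conservatively — the gene is excluded. Clusters
are connected components of the RBH graph across all genome pairs. The locus
filter for phylogenetics keeps **single-copy-complete** clusters: exactly
one member in every genome of the evaluation set. Completeness is judged
over the evaluation set only, which makes the filter monotone — adding a
genome can only shrink (or preserve) the retained set. A greedy longest-first
90%-identity clustering is provided for redundancy reduction of large
homolog sets before single-gene phylogenies.

# Alignment, trimming, supermatrix, tree

Each locus is aligned progressively: a 3-mer count distance feeds a UPGMA
guide tree, and profiles are merged by profile–profile Needleman–Wunsch
(affine gaps; average column-pair BLOSUM62 score; implemented in C++).
Gaps are only inserted, never residues changed, so ungapping any row returns
its input — a property tested directly.

Alignments are trimmed with a relaxed conserved-block filter. The exact rule
set (deliberately transcribable):

1. columns with gap fraction > 0.5 are removed;
2. a column is *conserved* if its most frequent residue covers > 50% of rows
   (*highly conserved* at ≥ 85%);
3. runs of more than 8 consecutive non-conserved columns are removed;
4. surviving blocks are trimmed to start/end on highly conserved columns and
   dropped below 5 columns.

The relaxed defaults aim to retain informative sites; all five parameters
are exposed. Trimming is applied per locus, then loci are concatenated into
a supermatrix with a partition map (1-based inclusive column intervals;
also written as a `PROT, locus = start-end` partition file alongside relaxed
PHYLIP, so external maximum-likelihood programs can be applied to the same
matrix).

Distances are Poisson-corrected protein distances $d = -\ln(1 - p)$ with $p$
the mismatch fraction over shared ungapped columns; pairs at $p \ge 0.95$
(the 20-letter saturation regime) are capped and flagged. Trees are built by
neighbor joining — a deliberate, documented substitution for likelihood tree
search: the claims consumed downstream (clade membership, support values)
are testable at desk scale with NJ, and the PHYLIP export preserves the ML
option externally. Negative NJ branches are clamped to zero with the deficit
moved to the sister edge, preserving path lengths through the node. Bootstrap
supports resample supermatrix columns with replacement; an internal edge's
support is the percentage of replicate trees containing the same bipartition
(branch lengths ignored, rounded half-up).

# Island delineation

Direct repeats are found by exact 16-mer seeding and maximal outward
extension (Hamming mismatches allowed up to a budget; default 0, i.e. exact
maximal repeats), keeping pairs ≥ 40 bp long separated by 5–200 kb. The
200 kb ceiling bounds the search and exceeds the largest island span the
package is designed around (~145 kb for ICE-type elements). Pairs contained
in longer pairs are suppressed.

A repeat pair with a copy overlapping an annotated tRNA becomes an island
call spanning **from the end of the proximal copy to the end of the distal
copy**: the intact tRNA stays outside the island and the duplicated target
site travels with it. When two candidate pairs share a tRNA the
longer-spanning pair wins; both are retained for inspection. Repeat pairs
touching no tRNA are reported but not called.

Two corroborating evidence layers:

* **Flanking synteny**: the `m_flank` (default 5) genes on each side of the
  island are mapped through ortholog clusters into a non-carrier relative;
  a contiguous colinear run with at most `gap_tolerance` (default 1)
  intervening genes is the signature of an empty integration site.
* **Anchor core expansion**: starting from the island's anchor genes (the
  perchlorate-reductase-like and chlorite-dismutase-like loci in the
  motivating system), walk outward gene by gene; a gene joins the shared
  core if its cluster occurs in ≥ 2 islands, and a walk stops after 3
  consecutive island-specific genes. Everything else is per-island
  accessory cargo.

Mobility classification is deterministic and total, with priority
tRNA-integrative > ICE > composite transposon > unknown:
tRNA-integrative requires the repeat/tRNA geometry plus a site-specific
recombinase inside the span; ICE requires conjugation and replication
markers; composite transposon requires flanking insertion-sequence genes
whose sequences are ≥ 95% identical over ≥ 500 bp. Markers are regex lists
over product annotations — a documented simplification of profile-based
searches, and configurable because annotation vocabularies vary. The
95%/500 bp thresholds are declared defaults: no quantitative standard for
"near-identical" IS copies exists in the source literature.

# SNP divergence contrast

Reference–query alignment uses maximal *unique* exact matches (k = 20) as
anchors — uniqueness avoids repeat-induced chimeric chains — merged along
diagonals and chained by a heaviest-colinear-chain dynamic programme
(weight = anchor length). Anchor gaps of equal length are paired base by
base; unequal gaps up to 5 kb are closed by global affine alignment;
anything else is flagged unaligned, so every reference base is assigned
exactly once. SNPs are mismatched aligned columns with unambiguous ACGT on
both sides, indel and `N` columns skipped.

Each SNP gets exactly one region label: `unaligned_adjacent` within 100 bp
of an unaligned block (draft-assembly caution), else `island`, else
`backbone`. Windowed histograms (default 500 bp, the classic island-plot
resolution) tile the island from its start; the final partial window keeps
its true effective length so window counts always sum to the region's SNP
total.

Frequencies divide SNP counts by **aligned** reference bp by default
(draft assemblies leave gaps; the total-length denominator is always
reported alongside). The backbone excludes the island interval. The
acquisition test is a one-sided exact binomial depletion test:
$p = P(X \le k_1)$, $X \sim \mathrm{Binomial}(n_1, k_2 / n_2)$ with
$(k_1, n_1)$ the island count and aligned length and $(k_2, n_2)$ the
backbone's. Classification: `recent_independent` when $p < 0.01$ and the
island/backbone frequency ratio is below 0.1; `ancestral_vertical` when the
ratio lies in $[0.5, 2]$; `indeterminate` otherwise. The thresholds are
declared defaults motivated by the ~200-fold contrasts this design is built
to detect, and are config-exposed; a two-sided variant is available by
flag. When several regions are tested in one run, Bonferroni correction
across regions applies; the single-island default needs none. A query in
which less than 5% of the island interval is alignment-covered (a
non-carrier, or an island lost in an assembly gap) reports an undefined
contrast rather than a misleading test on a few bases.

Coding effects of SNPs are annotated by strand-aware codon translation:
synonymous, nonsynonymous (with a `"X<pos>Y"` 1-based residue string),
nonsense (internal stop gained), start-loss (initiator no longer
ATG/GTG/TTG). CDSs whose length is not a multiple of 3 yield
`unclassified` rather than a guess.

# The simulator: what it emulates, and what it does not

`simulate_clade()` generates a small genus — by default 3 island carriers
plus 1 non-carrier relative — descending from one ancestor along a Yule
tree rescaled so every root-to-tip path equals `backbone_depth` (expected
substitutions/site; default 0.01, giving up to ~2% pairwise backbone
divergence, matching the strain-level divergence regime the method
targets). Sequences evolve under JC69, substitutions only: per branch the
event count is Poisson, sites are uniform with replacement (multiple hits
can collide and are accounted for in the truth tables), and each event
replaces the base by one of the three alternatives. Indels are deliberately
off — the downstream analysis counts substitutions — and no recombination,
gene gain/loss outside the island, rearrangement, or realistic codon usage
is modelled.

The island template carries the two anchor genes, a site-specific
recombinase, and optional conjugation or transposase cargo. Integration
inserts the island immediately 3′ of the target tRNA and duplicates the
tRNA's terminal 48 bp at the island's distal end — the single supported
integration geometry. Two transfer histories:

* **recent_transfer** — backbones diverge first; each carrier then receives
  the island having accrued only `island_residual` (default 5 × 10⁻⁵)
  substitutions/site since the transfer, so carrier-pair island divergence
  is ~0.01% while backbones sit near 2%;
* **vertical** — the ancestor carries the island before divergence, so
  island and backbone divergence are equal.

Pseudogenization inactivates island genes by a single base change
(start-codon loss or an engineered internal stop), mirroring the early
stages of cargo decay.

One deliberate construction detail: when the island's first or last spacer
base happens to equal the base flanking the corresponding repeat copy, the
*maximal* repeat would exceed the 48-bp duplication and the island boundary
would be ill-defined at the base level. The simulator therefore rewrites
that single spacer base at insertion. This keeps "boundary-exact recovery"
a well-posed property; real data offer no such guarantee, which is one
reason passing these tests bounds algorithmic correctness, not real-world
accuracy. Other gaps between simulation and reality: no indels or
rearrangements (so whole-genome alignment is easier than for true drafts),
no contig fragmentation (islands on contig ends are handled but not
stress-tested), uniform base composition, and island gene content drawn
from the same random process as the backbone.

# Numerical and scale choices

Defaults are desk-scale: 200 kb genomes with 150 genes and 4 tRNAs, 30 kb
islands with 25 genes — minutes-scale analyses that preserve the
island:genome ratio of the motivating system. The test-suite and
acceptance-script study sizes are the package's own choices: boundary
recovery runs at the full default scale (20 genomes); classification and
SNP-exactness properties run on 30 kb/8 kb carrier pairs, since they
measure rates and calls, not absolute lengths (100 simulations per
scenario); tree recovery uses 10 taxa and 60 single-copy 900-bp loci at
depth 0.05 — with protein distances (which hide synonymous changes) fewer
loci leave the shortest internal edges of a scaled Yule tree with only a
handful of expected changes, and recovery degrades. Every random stage
takes an explicit seed; there is no hidden global randomness, and the
pipeline's manifest checksums are reproducible under a fixed config.

Tie-breaking rules are documented where they matter: DP tracebacks prefer
diagonal, then one fixed gap direction; best-hit ties exclude the gene;
equal-score repeat candidates at a tRNA resolve to the longer span;
NJ inherits its implementation's agglomeration order, and permutation
invariance is tested up to relabelling on generic (tie-free) matrices.

# Known limitations

* NJ on Poisson distances replaces ML inference; supports and topologies
  are exchangeable with ML only in the easy regimes tested. The PHYLIP and
  partition exports exist precisely so ML can be run externally.
* Marker-keyword mobility classification inherits annotation quality; it
  does not detect unannotated transposases or recombinases.
* The SNP caller is substitution-only by design: indel-rich regions end up
  unaligned rather than called.
* Exact-repeat delineation (`max_mismatch = 0`) assumes the target-site
  duplication has not itself diverged; the mismatch budget exists but trades
  precision for sensitivity and is off by default.
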