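---
title: "Models and methods behind mtevo"
author: "mtevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtevo)
```

`mtevo` supports comparative studies of organellar genome reduction: mapping
gene repertoires onto a species phylogeny under a loss-only model, summarizing
annotated genomes, estimating per-site evolutionary rates for fast-site
filtering, and screening bootstrap tree sets for support and conflict. This
vignette records the models, conventions and design decisions, and what the
package's synthetic-data tests do and do not demonstrate.

## Loss-only (Dollo) gene-content reconstruction

**Model.** Mitochondrial genes are essentially never regained once lost from
the organellar genome, so gene content is modeled as a monotone process: every
gene is present at the root of the (rooted) species tree and may only be lost.
Presence is binary — multi-copy genes collapse to presence, and a matrix
column absent from every taxon is rejected at construction so "present at the
root" is always well defined.

**Reconstruction is forced, not heuristic.** Under no-gain, an ancestor
possessed a gene iff at least one descendant tip still carries it (otherwise
presence at the ancestor would require a regain somewhere below). Losses
therefore fall exactly on the branches subtending *maximal absent subtrees*.
This unique history is also the minimum-loss history; the test suite verifies
both uniqueness and minimality against an exhaustive enumeration of all loss
placements on hundreds of random instances (up to 6 tips and 12 genes, where
enumeration over all 2^edges loss sets per gene is feasible).

**Event counting.** The unit is the (gene, branch) pair: k genes lost on one
branch count k events. `parallel_losses()` reports genes lost on two or more
branches; `compare_rootings()` re-roots the unrooted topology on every (or a
chosen set of) edge(s), reruns the reconstruction, and ranks rootings by total
events. Re-rooting on a terminal edge places the root between that tip and the
rest, which is how "rooted within a lineage" is represented at the granularity
of a lineage-level tree. With two taxa the single edge admits only one
rooting, so all candidates coincide.

**Interpretation caveat.** Ancestral repertoire sizes computed from sampled
genomes are lower bounds on the true ancestral content: unsampled lineages can
only add genes to the union at a node. The package reports exact values for
the matrix it is given and leaves the sampling caveat to the analyst.

## The Discoba worked example

The packaged example carries the mitochondrial gene repertoires of the four
discobid lineages — Jakobida (67 genes), Tsukubamonadida (*Tsukubamonas
globosa*, 41), Heterolobosea (*Naegleria*, 42) and Euglenozoa
(*Trypanosoma*/*Leishmania* kinetoplast, 14) — restricted to functionally
assignable, vertically inherited protein-coding genes, organized by
taxon-sharing class: B (jakobid-only), C (jakobids + *Naegleria*), D
(jakobids + *T. globosa*), E (jakobids + *Naegleria* + *T. globosa*) and F
(all four lineages). The class sizes |B| = 20, |C| = 6, |D| = 5, |E| = 22 and
|F| = 14 are the unique solution of the published repertoire totals
(67, 41, 42, 14) together with the 47-gene union of classes C–F and the
28-gene union of C and E. Genes whose identity is published carry their real
ids (*secY*, *rpoA*–*rpoD*, *rpl18*, *rpl34*, *rps1*, *cox15* in B; *rpl19*,
*rpl35* in D; *atp1* in E; *cob*, *cox1*, *cox3*, *nad2*, *nad4* in F); the
remaining members carry synthetic placeholder ids (`setb_10`, ...), because
the full per-class gene lists are not reproduced here. Placeholder identity
does not affect any computed count.

Class A (*rps16*, *rpl36*) contains genes absent from every discobid but
retained in some non-discobid mitochondrial genomes; an optional outgroup tip
(`include_outgroup = TRUE`) carries all six classes so the root-ward loss of
class A becomes reconstructable. Tips are lineage-level; the Heterolobosea tip
holds the shared *Naegleria* repertoire and the Euglenozoa tip the
kinetoplastid one.

## Annotated genome statistics

**Coordinates.** Features use 1-based inclusive intervals in the GenBank
convention. On a circular genome an interval with start > end wraps the
origin and is unwrapped internally; multi-interval features are joined in
listed order and minus-strand features reverse-complemented, as in GenBank
`complement(join(...))`.

**Composition.** "Coding" is the union of CDS, rRNA and tRNA extents projected
on the reference strand; pseudogenes and `other` features count as noncoding.
That definition is a package choice — annotation-level statistics rarely state
one — and matches the intuition behind "X% of the genome is coding" for a
gene-dense organellar genome. A+T fractions are computed on the reference
strand, with `N` bases in the denominator. Interval algebra (union,
intersection) is delegated to `IRanges`; tests cross-check it against a
per-base brute-force oracle on random circular genomes.

**Codon usage** counts codons in the annotated frame on the coding strand. A
CDS whose joined length is not divisible by 3 is skipped with a warning (URF
boundaries are annotation-dependent, so a hard error would be hostile);
codons containing ambiguity characters are dropped; stop codons are counted
and also reported separately. Functionally unassigned reading frames (URFs)
are recognized by an id or product containing "URF" and can be excluded via
`include_urfs = FALSE`. The genetic code is the standard one (translation
table 1); alternative initiation codons are only *flagged* by
`nonstandard_starts()`, never translated differently.

**tRNA decoding coverage.** An anticodon (RNA, 5'→3', positions 34–36) reads a
codon when positions 35/36 pair Watson–Crick with codon positions 2/1 and the
wobble position 34 pairs according to a configurable rule table. Defaults
encode common organellar assumptions: G34 → {C, U}; U34 → {A, G}, extended to
all four bases of a family box (four synonymous codons) when superwobble is on
(default); C34 → {G}; A34 treated as inosine → {U, C, A} (default). The rule
table is explicit and overridable because real anticodon inventories vary and
published genome reports rarely state their pairing assumptions. Termination
codons are excluded (no tRNA reads a stop), and initiator
(formyl-methionine) tRNAs are excluded from elongation coverage, so AUG counts
as covered only when a non-initiator CAU anticodon exists. The report lists
uncovered codons and the amino acids having at least one uncovered codon —
in gene-dense mitochondrial genomes these typically flag tRNAs imported from
the cytosol or produced by editing.

## Site rates and fast-site removal

**Model.** Likelihoods use a reversible amino-acid model: exchangeabilities S
(Poisson/equal by default for transparent numerics; the published LG matrix is
packaged as plain text and loadable with `substitution_model("lg")`),
equilibrium frequencies π (model defaults, or empirical "+F" frequencies from
the alignment with a pseudo-count of 1 per residue to avoid zeros), and
discrete-gamma rate variation. Q = S·diag(π) is rescaled to one expected
substitution per unit branch length; P(t) = exp(Qt) comes from the spectral
decomposition of the π-symmetrized generator, exact for reversible models.
Category rates are the means of K equiprobable Gamma(α, α) slabs (so they
average exactly 1); K defaults to 4. The shape α is a required input —
typically taken from a prior ML fit — with an optional bounded 1-D ML search
(`estimate_gamma_shape()`, golden-section via `optimize()` on [0.05, 20]).

**Per-site rates.** `site_log_likelihoods()` runs Felsenstein pruning per
category with per-node rescaling (gaps and missing residues contribute
all-ones partials); the conditional mean rate of site *i* is
r̂ᵢ = Σₖ rₖ·Lᵢₖ / Σₖ Lᵢₖ with equal category priors. Among estimators offered
by rate-estimation tools, the conditional (posterior) mean is implemented
here; results are bounded by the smallest and largest category rate. An
all-gap column carries no information: its rate is reported as 1.0 with a
warning. Pruning is verified to 1e-9 against exhaustive summation over all
internal-state assignments (≤ 5 taxa) and against the 20-state Poisson
closed form P_same(t) = 1/20 + (19/20)·e^(−20t/19) on two taxa.

**Removal series.** Sites are ranked *once* by decreasing r̂ (ties broken by
original column index, ascending); the k-th filtered alignment drops the top
k·step sites, so the series is nested. Rates are deliberately not recomputed
after each removal — the procedure mirrors the common practice of filtering a
fixed rate profile in fixed-size increments (the default step is 1000
positions) — and original column indices are carried in the output metadata
for any downstream tree builder. Tree search and bootstrapping themselves are
out of scope: the module consumes tree files and produces filtered
alignments.

## Clade support and the conflict screen

`clade_support()` counts, in unrooted semantics, the fraction of trees in
which a taxon subset forms one side of a bipartition; it is invariant under
re-rooting, single tips score 1 by convention, and the empty set or the full
taxon set is rejected. `conflict_screen()` reads support values from internal
node labels (each label supports the split separating that node's descendants
from the rest; the duplicate split at a binary root is deduplicated) and
flags, at a threshold of 70% by default, splits incompatible with an accepted
group G: after restricting to shared taxa, a split conflicts when G and its
complement each intersect both sides. Candidate offenders are the smaller of
the two fragments into which the split cuts G — both when tied — which is the
natural shortlist of contaminant/paralog candidates to inspect.

## Synthetic-data generators

The generators produce data with exactly the statistical structure each stage
assumes, plus the ground truth, so the pipeline is testable without downloads.
All take a `seed` and restore the caller's RNG state; the same seed gives
byte-identical output.

**Loss histories** (`simulate_loss_history()`) draw, per gene, an independent
Bernoulli loss on each branch (given presence at the branch's parent) with a
per-branch probability — event-based rather than a continuous-time rate,
matching the event-counting model above. Genes lost from all tips are redrawn
by rejection, keeping per-branch marginals interpretable at the cost of a
small upward bias under extreme settings; configurations in which all-tip
absence is certain are refused. A simulated history is identifiable from tip
data only if every surviving node retains the gene in some descendant tip:
sibling losses blanketing a whole clade are indistinguishable from one
earlier loss (reconstruction then reports fewer events, as parsimony should).
The recovery test filters on this condition using the simulator's truth
alone.

**Alignments** (`simulate_alignment()`) draw root states from π and evolve
them down the tree with P(Q·t·rᵢ) per branch and per-site true rates rᵢ
(explicit, or i.i.d. gamma draws). The two-taxon mismatch fraction is checked
against the Poisson closed form at 10⁵ sites.

**Toy genomes** (`make_toy_genome()`) plant CDS/rRNA/tRNA features on a
random AT-biased background so that the coding fraction is achieved *exactly*
(a tRNA absorbs the modulo-3 remainder of the CDS budget), one designated CDS
carries a nonstandard start codon, a pseudogene sits in noncoding sequence,
and each planted CDS–CDS overlap is the 4-bp `..A|TGA..` motif in which the
downstream gene's ATG overlaps the upstream gene's TGA stop — the classic
gene-dense organellar arrangement. On circular genomes the finished layout is
rotated so one CDS wraps the origin, exercising the coordinate unwrapping.
Ground truth (composition, per-codon tallies, overlap table, anticodon set)
is computed on the linear layout by direct base-vector bookkeeping before
rotation, independent of the package's interval and strand machinery.

What the generators do *not* emulate: RNA editing and multipartite
(maxicircle/minicircle) genome architectures, realistic tRNA secondary
structure or full anticodon inventories, alignment gaps, among-lineage
compositional heterogeneity, and model misspecification (alignments are
simulated under the same family of models used for estimation). Passing tests
therefore demonstrate algorithmic correctness and internal consistency, not
robustness to the violations real data bring.

## Test design choices and problem sizes

Tests run at desk scale: Dollo oracle equivalence on 200 random instances
(≤ 6 tips, ≤ 12 genes), likelihood oracles on ≤ 5 taxa, composition
identities on 100 random toy genomes (0.7–1.2 kb), and a single 16-taxon ×
500-site alignment for rate recovery. For the recovery experiment the planted
two-class rates are 0.2 and 3.0 with a fast-class fraction of 0.35, and the
removal check uses a 100-site first block. Two definitional notes, fixed
before the tests were written: (i) Spearman correlation against a two-valued
truth has a ties ceiling of about 250·√(f(1−f))/sd(1:500) at 500 sites — at
f = 0.35 the ceiling is ≈ 0.83, and the estimator attains it exactly
(perfect rank separation of the two classes); a small minority class would
cap the ceiling below any meaningful threshold no matter how well rates are
recovered. (ii) Enrichment of the fast class in the first removed block is
reported as the fold ratio of its frequency among removed sites to its
frequency among retained sites; at perfect separation this is 5.3-fold under
the chosen mix.

The per-branch loss probability used in simulation-recovery tests is 0.25 —
high enough that parallel losses occur regularly on 5-tip trees, low enough
that most genes survive somewhere.

## Known limitations

* Presence/absence only: no copy number, no gene gain or transfer (laterally
  acquired genes must be excluded from the matrix upstream, as is standard).
* The loss-only reconstruction is exact *given* the tree; topological
  uncertainty must be handled by rerunning on alternative trees (the rooting
  comparison automates only the root position).
* Site-rate estimation conditions on a fixed tree and branch lengths;
  uncertainty in either is not propagated.
* The genome reader supports single-record FASTA plus a simple 7/8-column
  feature table; GenBank flat files should be converted to that table
  upstream.
* De novo gene finding, ortholog assignment, tRNA structure prediction,
  alignment construction, ML/Bayesian tree search and RNA-editing inference
  are out of scope.
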