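---
title: "Methods: inferring conserved motif-gene networks across genera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring conserved motif-gene networks across genera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crossnet` infers motif-gene regulatory associations conserved between
two nematode genera. This vignette is the package's account of the
models and procedures it implements, the parameters that matter, the
numerical choices made, and what the synthetic-data tests do and do not
demonstrate.

## The comparative strategy and its assumptions

Non-coding regulatory DNA diverges too fast to align between distant
genera, but within a genus it still aligns well. The package therefore
assumes:

* within-genus alignments (or a precomputed conserved-element BED)
  identify candidate regulatory sequence;
* 1:1:1 orthologs with conserved developmental expression are enriched
  for shared regulation, so their conserved non-coding neighborhoods
  are a sensible motif-mining substrate;
* a motif-gene association found independently in both genera, near
  genes of the same biological process, is evidence of a conserved
  regulatory relationship even though the motif instances themselves
  are not alignable across genera.

The unit of cross-genus comparison is never raw sequence: it is the
(motif, GO term, ortholog set) triple.

## Expression conservation

Replicates are averaged to per-stage means before any thresholding;
all rules operate on the four-stage mean profile (stages *e*, *f*,
*i*, *a* in developmental order).

**Binarized rule.** A stage is "on" at `on_fpkm = 10` (an averagely
expressed gene, FPKM/TPM units); the partner species must reach
`relaxed_fpkm = 5` at the same stages. We apply the rule symmetrically
(both directions must hold): for a species *pair* a directional rule is
ill-defined without naming a reference species, and symmetry makes the
call an equivalence-like relation. Orthologs off everywhere in both
species carry no stage-specific information and are returned as
`not_assessed`, excluded from conservation percentages.

**Cosine rule.** Profiles are compared by cosine similarity; an
ortholog is conserved when similarity is strictly greater than
`cosine_min = 0.95`. Stage means (not individual replicates) are used
as the vector coordinates: replicate-as-dimension mixes technical
structure into a biological comparison and makes the result depend on
replicate pairing, which is arbitrary across species. Cosine is
scale-invariant, which matches the FPKM/TPM setting where per-sample
normalization constants differ. Proportional vectors return exactly
1.0: the implementation detects Cauchy-Schwarz equality on the squared
forms (`(u·v)^2 >= |u|^2 |v|^2`) before taking square roots, so the
boundary case is not subject to `sqrt()` rounding. A zero vector has no
direction; the function returns `NA` and the caller reports
`not_assessed`.

**Stage-set assignment.** Conserved orthologs get the label of the
stages contributing at least `contribution_min = 10%` of their combined
profile, written in developmental order (e.g. `"ef"`). The combined
profile is the mean of the two species' sum-normalized profiles — the
analysis names no reference species, and normalizing first prevents the
more highly expressed species from dominating. Only sets with strictly
more than `min_set_size = 30` genes proceed to motif mining; smaller
sets stay in the full report.

## Conserved non-coding sequence

**Windowed conservation caller.** Over a gapped pairwise alignment, a
column is conserved iff some window of 30 consecutive columns covering
it contains at least 23 identical non-gap matches. Gap columns never
count as matches; maximal conserved runs are merged and reported in the
ungapped coordinates of the first sequence. This windowed caller is the
package's conservation primitive; a phylogenetic hidden-Markov
conserved-element track can be supplied instead as a BED file and used
interchangeably.

**Coding/non-coding partition.** Conserved bases overlapping any
annotated exon, UTR, or transcript-derived exon are coding-conserved;
all remaining conserved bases are non-coding. The partition is at base
resolution, so an element straddling an exon boundary is split; the
two classes always cover every conserved base exactly once (asserted in
the tests).

**Region extraction.** Non-coding conserved pieces intersecting
`[gene start − 3000, gene end + 3000]` are clipped to the intersection;
pieces of 8 bp or shorter are discarded (strictly more than 8 bp
required). The ±3 kb window covers the gene body, hence also introns.
Flanks are measured from annotated gene boundaries (not transcription
start sites, which draft annotations rarely nail down) and are
strand-agnostic.

**Coordinates.** Internally all intervals are 1-based closed, the
Bioconductor convention, carried in plain tibbles and converted to
`GRanges` for interval arithmetic; `rtracklayer` performs the
conversions to BED (0-based half-open) and GFF3 (1-based inclusive) on
IO. Using the ecosystem's native convention removes a whole class of
off-by-one errors that hand-rolled 0-based arithmetic invites in R.

## ZOOPS-EM motif discovery

The model: each sequence independently contains one motif site with
probability γ (estimated), placed uniformly over eligible windows on
either strand, or none with probability 1 − γ. Site columns follow the
position probability matrix; all other positions follow the
mononucleotide background estimated from the input.

* **Seeding.** Every distinct observed subsequence of the candidate
  width is a potential EM start, initialized at probability 0.7 for the
  seed letter and 0.1 otherwise. When there are more candidates than
  `n_seeds`, the most frequent words are kept first — recurrence is
  exactly the signal sought, and frequency-ranked seeding also resolves
  the motif-phase ambiguity (a shifted seed converges to a shifted,
  weaker optimum). Ties are broken by a seeded draw. Seeds are drawn
  from the content-sorted sequence set, so results are invariant to
  input order.
* **Pre-screen.** Each seed is scored by one E-step likelihood
  evaluation; the best `n_keep` per width get a full EM run
  (convergence: relative log-likelihood change < `tol = 1e-4`, at most
  `max_iter = 100` iterations). The EM objective is monitored and must
  be non-decreasing (asserted in tests to 1e-6 relative tolerance —
  the small slack covers the background-proportional pseudocounts of
  total mass 0.01 per row added at each M-step to avoid zeros).
* **Significance and stopping.** A fitted motif's score is
  −(log-likelihood ratio of ZOOPS over background-only) +
  log(number of seed starts evaluated) — an approximate Bonferroni
  penalty for the search. Lower is better; motifs are reported while
  the score is negative, up to `nmotifs`. After each motif, its sites
  (combined-strand responsibility > 0.5; strands must be pooled per
  window or palindromic motifs, whose responsibility splits evenly
  across strands, would report no sites) are masked so subsequent
  motifs cannot reuse them.

## Scanning with exact p-values

Scores are log2 odds of the pseudocount-regularized PWM over the
background. The null distribution of a random background word's total
score is computed exactly by dynamic-programming convolution over
scores discretized at `granularity = 1e-3` bits; `p(s) = P(score ≥ s)`.
Observed window scores sum unrounded cell scores, so they can land a
few grid steps outside the DP support; the lookup clamps into the
support, keeping p in (0, 1]. The DP equals brute-force enumeration
over all 4^w words on the same grid (asserted to 1e-10 for widths ≤ 6).
`N` bases contribute 0 bits (background-expected). Both strands are
scanned; per motif, Benjamini-Hochberg q-values are computed across
every scanned position of every sequence, and hits are reported at
q ≤ 0.3.

## Motif comparison and filtering

Motif pairs are aligned ungapped at every offset/orientation with at
least 5 overlapping columns and scored by summed column-wise Pearson
correlation (columns with zero variance compare as 1 when identical,
else 0). The p-value comes from a seeded permutation null (column
shuffles of the target; `p = (1 + #null ≥ observed)/(n_perm + 1)`, so p
can never be 0). Redundancy removal is greedy and deterministic:
matching pairs are processed in (p, id) order and the member with the
worse (higher) significance score is removed, ties broken by id; the
procedure is idempotent and leaves no matching pair (both asserted).
Motifs must map (≥ 1 passing hit) in **both** species to be retained —
the conserved networks need associations on both sides, so the
one-species reading would only defer the same filtering; the
`require = "either"` flag restores the laxer reading. Database matching
reports each query's best match at p < 1e-4 and e < 0.5, with
e = p × database size; its default `n_perm = 10^4` is the minimum that
can resolve the p threshold.

## Enrichment, networks, control

Motif hits are associated with the nearest gene (genomic distance; 0
when overlapping; equidistant ties all retained). Each motif's gene set
is tested per GO term by the one-sided hypergeometric tail (identical
to Fisher's exact over-representation test), computed by
`stats::phyper` and verified against explicit binomial-coefficient
summation to 1e-10. Annotations are used as given — no GO-graph
ancestor propagation.

The BH correction family is configurable: by default q-values are
computed across the terms present in the study set (the per-result-list
convention); `fdr_family = "all"` corrects across every annotated term
in the population, the convention of genome-annotation enrichment
suites which test the full vocabulary. The randomized control defaults
to `"all"` for this reason. For the planted-signal analyses the choice
is immaterial (planted enrichments are orders of magnitude below either
cutoff).

(motif, term) pairs significant at FDR < 0.05 in both species form
candidate conserved associations; the shared-ortholog fraction is
computed in both directions and the minimum is compared against the 30%
threshold (the conservative reading — the direction is otherwise
arbitrary). Category networks connect motifs to the shared 1:1 ortholog
targets of passing pairs; the degree ≥ 5 view is a single-pass display
filter on degrees computed in the unfiltered network, not iterative
pruning, and both views are exported.

The randomized-GO control permutes whole per-gene term sets among
previously annotated genes (unannotated genes stay unannotated), which
preserves the multiset of per-gene term-set sizes and every term's gene
count, then re-tests every motif gene set per randomization and counts
runs where any category term reaches FDR < 0.05.

## The synthetic world

`simulate_world()` generates three species in two genera: two congeners
(`g1s1`, `g1s2`) with expression and one genome, and an outgroup
(`g2s1`) with expression and a genome. Defaults: 300 orthologs, 2
replicates, conserved fraction 0.5, multiplicative lognormal expression
noise with log-scale SD 0.05, background GC 0.455 (a realistic nematode
genome composition), two planted motifs of width 8 tied to two
GO categories of 50 genes each.

Choices worth stating:

* **Profile family.** Stage profiles are Dirichlet(0.3) draws —
  concentrated, as stage-specific genes are; category genes share a
  fixed concentrated profile per category so they land in one
  stage-specific set, mirroring how co-regulated genes co-occur in
  expression clusters. The real data's profile distribution is unknown;
  this is a modeling choice.
* **Divergence model.** Divergent orthologs have the stage axis of the
  second congener's profile permuted, which changes the profile shape
  without changing total expression. The permutation is re-drawn until
  the permuted profile is not cosine-conserved (≤ 0.95) with the
  original — the same threshold the classifier uses — so the truth
  label "divergent" is well-defined rather than an accident of a
  symmetric profile.
* **Expression level.** Total expression is shared across species per
  ortholog (lognormal around 100 FPKM; category genes around 300), so
  at zero noise both conservation methods recover 100% by construction.
* **Genomes.** Genes are laid out sequentially with wide intergenic
  gaps (more than twice the block flank), three exons, terminal UTRs;
  one conserved non-coding block upstream of each gene and one in its
  first intron. Planted motif instances are written into upstream
  blocks of category genes (exact counts at `planting_rate`, same gene
  subset in both genome species, random strand). Wide gaps make
  nearest-gene association unambiguous, which is what lets planted-
  recovery tests measure the pipeline rather than annotation noise.
  Every block also gets a mutated partner copy (5% substitutions) so
  the windowed conservation caller is exercisable on generator output.
* **What it does not emulate.** Read-level sequencing noise, repeats,
  indels and alignment error, GO-graph structure, motif turnover and
  degenerate (non-consensus) planted sites. Passing the planted-
  recovery tests therefore shows the pipeline's machinery is correct
  and sensitive under clean conditions; it does not certify recall on
  real, noisy assemblies.

## Problem sizes and test design

The test-suite simulations are sized for a single CPU: worlds of
80-120 orthologs for module tests, the 300-ortholog default world for
the conservation-recovery and end-to-end planted-recovery checks,
discovery with one width (the planted width 8), a few hundred seed
starts and 20 seeded repetitions for the recovery-rate check. Pipeline
defaults (`pipeline_params()`) carry the published thresholds for every
scientific parameter and desk-scale search effort (`nmotifs`,
`n_seeds`, `n_keep`) suited to these worlds; for larger real inputs,
raise the search effort and widen `minw:maxw` to the full 6-12.

The null world for the randomized-control reference run uses 1,000
genes, category terms on 5 genes each (0.5%), a 2,000-term vocabulary
with ~6 terms per annotated gene, and 30 motif sets of ~30-40 genes.
These proportions mirror a real annotation's sparsity — specific GO
terms annotate far below 1% of a genome, and any one gene set samples a
small slice of a large vocabulary — which is the regime in which the
control's zero-recovery behavior is meaningful. With dense category
terms (tens of percent of genes) chance overlaps reach nominal
significance occasionally, and a zero count would not be expected of
any implementation.

## Known limitations

* The EM finder reports ungapped, fixed-width motifs only; no OOPS or
  multiple-occurrence models, no position-specific priors.
* The motif significance score is a likelihood-ratio surrogate, not a
  calibrated E-value; it orders motifs well but its absolute scale is
  not comparable across datasets of different size.
* The permutation null for motif-motif comparison is coarse at small
  `n_perm`; database matching at p < 1e-4 needs `n_perm ≥ 10^4`.
* Nearest-gene association ignores strand and regulatory domain
  boundaries (TADs, insulators) — as does the underlying strategy.
* `motif_arrangement` uses gene-relative offsets with a 200 bp default
  tolerance; the original assessment of arrangement conservation was
  visual, so these parameters are necessarily this package's own.
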