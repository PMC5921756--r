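---
title: "Methods: characterizing an ARF gene family with arfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an ARF gene family with arfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfkit)
```

# Scope

Auxin Response Factors (ARFs) are plant transcription factors with a canonical
three-part architecture: an N-terminal DNA-binding domain (DBD, a B3 subdomain
followed by an AUX_RESP subdomain), a variable middle region (MR) acting as an
activation or repression domain, and a C-terminal dimerization domain (CTD,
subdomains III and IV) through which Aux/IAA repressors sequester ARF
activators. `arfkit` implements the analyses that make up a genome-wide
characterization of such a family: family-table genomics, duplication dating,
protein classification, distance-based phylogeny, promoter cis-element
enrichment, and RT-qPCR normalization. The package ships a hand-curated
transcription of a 24-member chickpea ARF family table and its 10-element
promoter motif panel as plain-text fixtures, plus seeded generators that
produce synthetic inputs with the statistical structure each stage assumes, so
the entire pipeline runs and is tested offline.

# Family-table genomics

Coordinates are 1-based and fully closed; genes without an assembly placement
carry the reserved chromosome label `UNPLACED` and are excluded from
distribution fractions.

**Tandem clusters.** The tandem rule is: at least two genes on one chromosome,
consecutive neighbors (after sorting by start) separated by less than a window
(default 250 kb). The gap is end-to-start distance between coordinate-sorted
neighbors. The windowed-run definition makes the result independent of input
order, and shrinking the window can only shrink cluster membership. Strand is
ignored (reference clusters mix orientations). Overlapping neighbors get gap 0
with a warning rather than an error, since assembly overlaps are common and
still indicate adjacency. On the packaged table this yields exactly two
two-gene clusters with gaps of 183,779 and 184,137 bp.

**Duplication dating.** Divergence time is T = Ks / (2γ) with γ = 6.1e-9
synonymous substitutions per site per year (the standard eudicot rate),
reported in million years at full precision; rounding to integer Mya happens
only in presentation. Selection mode from Ka/Ks uses a configurable neutral
band (default ±0.05 around 1), because the textbook trichotomy puts neutrality
on a measure-zero point; Ks = 0 yields an explicit undefined-ratio flag rather
than a fabricated mode. Ka/Ks values are inputs (they come from codon-level
resources outside this package's scope).

# Protein features

**Molecular weight** is the sum of average residue masses plus one water
(18.015 Da), in kDa. **Isoelectric point** uses the Bjellqvist pKa set — the
set behind the ExPASy Compute pI service, which the reference analysis used —
over the termini (N-terminal pKa depends on the first residue) and the side
chains of D, E, C, Y, H, K, R. The net-charge function is strictly decreasing
in pH, so bisection to 0.001 pH units is guaranteed to converge; tests compare
it against an exhaustive grid scan of the same charge function.

**Architecture classes.** Given domain spans (B3, AUX_RESP, and optionally
III/IV; spans must be ordered and non-overlapping), proteins are FULL (III and
IV), TRUNCATED_III_ONLY, or DBD_ONLY. IV without III violates the ordered
domain model and is an error, not a class.

**Middle region and regulatory role.** The MR is taken as the residues
strictly between the AUX_RESP end and the III start (to the C-terminus for
DBD-only proteins). The composition call computes, for the residue sets
{Q,S,L}, {S,P,G,L} and {G}, a signature score = summed observed MR frequency /
summed background frequency. A protein is called an activator only when the
{Q,S,L} score is the strict maximum *and* observed glutamine exceeds its
background — glutamine enrichment being the recognized hallmark of ARF
activators; ties go conservatively to repressor. Non-activators are
SPGL-repressors when any CTD subdomain is present and no-CTD repressors
otherwise. The background defaults to the mean residue frequencies of the
protein set under analysis (configurable). The reference publication gives no
quantitative threshold for "rich" regions, so this rule is a design decision
of this package; per-protein parity with the reference's calls is checked on
a schedule-matched synthetic family, not re-derived from unavailable
sequences. The packaged domain-span table is likewise a synthetic stand-in
(marked `synthetic` in its filename) built to satisfy every constraint the
reference text states (which three proteins are III-only; every protein under
670 aa DBD-only; every protein over 725 aa CTD-bearing; 15/3/6 class totals).

# Phylogeny

Distances are proportions of differing sites with **pairwise deletion** of
gap columns, Poisson-corrected as d = −ln(1 − p). Pairwise deletion is a
documented divergence from the reference tool's complete-deletion default: the
family contains heavily truncated members, and complete deletion would discard
most columns of a mixed alignment. Saturated pairs (p ≥ 1) become infinite
distances and must be resolved before tree building (the functions say so
rather than guessing).

Neighbor joining is implemented directly (Saitou–Nei Q-matrix agglomeration)
with two determinism rules: ties in the Q minimum break to the lowest
(row, column) pair in the current ordering, and negative branch lengths are
clamped to zero with the deficit moved to the sibling edge, preserving path
lengths. On additive matrices the generating topology is recovered exactly
(a brute-force least-squares quartet oracle and 200 random 4–8 taxon cases
check this).

Bootstrap supports resample alignment columns with replacement, re-run the
whole distance pipeline, and report for each internal edge of the full-data
tree the percentage of usable replicates containing the same bipartition
(replicates with incomparable or saturated pairs are skipped and counted).
Supports are mapped onto the full-data tree rather than a majority-rule
consensus, matching common practice. Sister pairs are cherries whose
subtending edge support strictly exceeds the threshold (default 65%).

The group I/II exon-count contrast is a two-sided Welch t-test; group
membership is an explicit input because it comes from the tree annotation,
not from the table.

# Promoter cis-element enrichment

Motifs are IUPAC-degenerate strings scanned on the forward strand only
(literature cis-elements are defined on the sense strand; a reverse-strand
scan can be added by the caller), case-insensitively, with overlapping matches
each counted. Ambiguity codes in the *subject* never match.

The null model is zero-order i.i.d. with p(G) = p(C) = gc/2 (default gc =
0.28, the reference promoter set's average; the reference also quotes 27.8%
in a second place — the Methods value 0.28 is used). Expected total
occurrences are Bernoulli: match probability × Σ(Lᵢ − m + 1). The enrichment
factor is observed/expected. Note that the reference's printed expected
counts follow *its own* promoter nucleotide frequencies, which are not
published; recomputation under the symmetric GC model reproduces some printed
rows to ~1% but deviates up to ~60% on others, so printed-value parity is a
known limitation rather than a correctness check.

Monte-Carlo p-values simulate control sets (default 2000 sets of 23 × 1500 bp)
and use the set-level total occurrence count as the statistic with the add-one
correction p = (1 + #{sets ≥ observed}) / (1 + n_sims), which is never zero
and is uniform under the null up to discreteness. All motifs of a table share
one stream of control sets. Positional density divides the promoter window
into 100-bp bins (TSS-relative, −L…−1) and can overlay a null envelope (the
per-bin 95th percentile over simulated sets scanned with the same motifs).

# RT-qPCR normalization

Amplification efficiency comes from (1 + E) = 10^slope. Relative quantities
are (1+E)^(ΔCq) against the calibrator sample. geNorm M for a candidate
reference is the mean, over the other candidates, of the standard deviation
across samples of the pairwise log2 ratio; candidates are eliminated worst
first down to a pair, and qBase-style CVs are computed on quantities
normalized to the selected references. Heterogeneous panels conventionally
accept references with M < 1 and CV < 0.5.

NRQ divides each target's relative quantity by the geometric mean of the
reference quantities in the same sample, which cancels sample-wise loading
shifts exactly (a tested invariance); the calibrator row is 1 by
construction. Error propagation works on the log2 scale: variances of the
target and reference ΔCq terms (sample and calibrator), each scaled by
log2(1+E)², combine in quadrature, references down-weighted by 1/n_ref².
Replicate Cqs are averaged before quantity computation and their *technical
variance is pooled per assay across samples* before propagation — with two or
three technical replicates a per-cell standard deviation is far too unstable
to propagate, while technical noise is a property of the assay. Cq values
beyond 40 cycles are treated as not detected (NA), excluded from means and
never imputed. The 3′:5′ integrity ratio is 2^(Cq5′ − Cq3′) under the
comparative-Cq convention (E = 1 for both fragments), with verdicts OK
(< 3.8), BORDERLINE (3.8–4.4), INADEQUATE (> 4.4).

Expression matrices are log2 NRQs; clustering uses 1 − Pearson distance with
average linkage (both configurable; the reference names only its computing
environment); ordination is the SVD of the column-centered matrix with
variance fractions sᵢ²/Σs², the interpretation consistent with quoting a
"fraction of total variance" per dimension.

# What the synthetic generators emulate — and what they do not

Every generator is bit-reproducible under a seed, and each draws from its own
named substream of the user seed, so adding one generator to a script never
shifts another's output.

* `gen_promoters` emulates the control-set regime (n = 23, 1500 bp, GC 0.28)
  with optional motif planting (copies never overlap each other). It does
  **not** model dinucleotide structure, CpG effects, repeats, or real promoter
  base composition beyond GC — so a green enrichment test establishes correct
  counting and calibration under the stated null, not biological realism.
* `gen_protein_family` produces proteins whose domain layout and MR
  composition follow the requested schedule exactly; real MRs are far less
  stereotyped, so recovery of the schedule validates the classifier's logic,
  not its biological accuracy.
* `gen_alignment_on_tree` uses the uniform-exchange (Poisson) substitution
  model — deliberately the same model family the Poisson correction inverts —
  with substitution probability 1 − exp(−b·20/19) per site and branch. Green
  recovery tests therefore establish internal consistency, not robustness to
  among-site rate variation or non-uniform exchangeabilities.
* `gen_cq_table` inverts the quantification model with lognormal per-sample
  loading and Gaussian replicate noise. The acceptance-level recovery
  experiment uses 0.1-cycle noise, two references, and **six** technical
  replicates: with two or three replicates the pooled variance estimate has so
  few degrees of freedom that a ±2-SE band mathematically under-covers 95%
  (t- versus z-tails) for any correct implementation, so six replicates are
  used to test what the property is about — the propagation algebra. The
  recovery check is made on the log2 scale the errors are propagated on.
* `gen_kaks_pairs` draws Ks uniformly on the 0.59–1.64 range (dating to
  ~48–134 Mya under the default clock) and ratios around a purifying mean of
  0.19 with an optional positively selected component.

# Numerical choices and degenerate inputs

* pI bisection tolerance 0.001 pH; agreement with the grid oracle within
  0.002.
* Neutral Ka/Ks band ±0.05; divergence times stored at full precision.
* NJ ties by lowest index pair; negative branch lengths clamped with deficit
  moved to the sibling edge; three remaining nodes resolved by the three-point
  formulas.
* Monte-Carlo p-values use the add-one correction; enrichment with expected
  0 is flagged NA, never Inf.
* Empty MR, IV-without-III, all-unplaced tables, all-undefined ratio sets,
  constant matrices for ordination: all are explicit errors naming the
  problem, not silent results.

# Known limitations

* The reference's printed expected motif counts and per-motif p-values cannot
  be reproduced (their exact counting convention and promoter base
  frequencies are unpublished); the corresponding check is kept in the test
  suite and fails openly on the irreproducible rows.
* The 71-taxon comparative tree, figure-level outputs, and the variance
  fractions of the unreleased 22-sample expression panel are structural
  references only; the package tests the machinery on synthetic data instead.
* Ka/Ks estimation from codon alignments, domain detection, and multiple
  alignment are out of scope: spans, alignments and pair values are inputs.
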