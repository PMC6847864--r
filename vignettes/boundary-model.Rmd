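---
title: "Probabilistic refinement of mitochondrial gene boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic refinement of mitochondrial gene boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoboundaries)
```

## The problem

Homology search localizes the 13 protein-coding genes (PCGs) of a metazoan
mitochondrial genome reliably, but the profile-HMM hits it produces are
systematically too short: the precise start and stop codon positions are
left open.  Mitochondrial genetics makes those positions genuinely hard to
pin down.  Translation initiation uses different codon sets under the
different NCBI mitochondrial code tables — and, in several invertebrate
lineages, codons not listed in any table; termination frequently relies on
*incomplete* stop codons (a terminal `T` or `TA` completed to `UAA` by
post-transcriptional polyadenylation), so the coding region need not end in
a stop codon at all.  A fixed search window around the approximate hit
boundary combined with the binary NCBI tables (the legacy strategy
retained here as `legacy_predict()`) mispredicts a large fraction of
boundaries.

## The model

Every boundary decision combines three empirically fitted factors,
stratified by (NCBI code table, gene):

* **φ — codon usage.**  `fit_boundary_model()` counts, over a reference
  annotation set, how often each codon is annotated as a start codon, as a
  (possibly incomplete) stop codon, and as an internal codon.  Start
  codons with frequency below 0.01 are discarded as probable annotation
  errors; a codon is accepted as a stop codon only if its internal
  frequency is below 0.001 (a codon that routinely appears in-frame inside
  genes cannot terminate them).  Incomplete stops are tracked under the
  pseudo-codons `TA-` and `T--`.
* **λ — gene length.**  The reference CDS lengths (nucleotides, one per
  species, including the possibly incomplete stop) give an empirical
  two-sided p-value λ(l) = 2·min(L≤, L≥)/(L≤ + L≥), where L≤ and L≥ count
  reference species with gene length at most / at least l (ties count on
  both sides, exactly as the estimator is defined).  Typical lengths score
  near 1; lengths outside the observed range score 0.
* **δ — model-projected distance.**  A candidate codon index p is
  projected onto the query-model axis through the hit geometry
  (r_s(p) = q_s + (q_e−q_s)/(s_e−s_s)·(p−s_s)) and scored
  δ_s(p) = 1 − r_s(p)/l_q; δ_e is the mirror image for the 3′ boundary.
  Because the hits are biased short, positions outside the hit interval
  score δ = 1 rather than being penalized.

Candidate starts are all in-frame codons with φ_s > 0 between the nearest
upstream in-frame full stop codon (exclusive — it delimits the open
reading frame) and the hit's center codon; candidate stops run from the
center to the nearest downstream full stop codon (inclusive).  At every
stop-side position, incomplete candidates are also emitted wherever the
sequence offers a `TA` or `T` prefix.  A specific full stop codon is a
1-in-64 event but a `TA` prefix is 1-in-16 and a `T` prefix 1-in-4, so the
stored incomplete frequencies are divided by 3 and by 12 respectively:
relative to the full codon, TA is 4× and T 16× easier to hit by chance,
and TAA / TAN are already represented among the full-codon candidates.
The predicted pair (s, e) maximizes

δ_s(s) · φ_s(s) · δ_e(e) · φ_e(e) · λ(3(e−s) + offset(e))

subject to the tRNA punctuation constraint: a candidate CDS span that
would swallow a whole tRNA locus is forbidden (partial overlaps are
normal in mitogenomes — atp8/atp6 famously overlap — and stay allowed).
If a candidate set is empty, or every admissible product is zero, the
corresponding boundary falls back to the approximate hit position; the
two fallbacks are independent.

## Numerical and design choices

* **Coordinates.**  Everything internal is 0-based half-open on the
  forward strand; BED-native, and arithmetic stays off-by-one-free.  The
  δ computation runs in codon units against amino-acid query columns so
  that r and l_q share an axis.  Origin-crossing features on circular
  genomes keep `start < end` by letting `end` exceed the genome length,
  with modular extraction.
* **The 3′ distance factor.**  A direct transcription of the r_e line
  would reuse the 5′ offset (l_q − q_s) and *decrease* towards the 3′
  end, going negative at p = s_e for typical hits — inconsistent with the
  stated intent that δ approach 1 at the boundary.  The default is
  therefore the mirrored form r_e(p) = (l_q − q_e) + slope·(s_e − p); the
  transcription-faithful variant remains available via
  `literal_delta_e = TRUE` for comparison.
* **Center codon** is `floor((s_s + s_e)/2)`, kept in frame by working in
  codon indices throughout.
* **Scan termination.**  On circular genomes without an in-frame stop the
  candidate scans cap at one genome length.  On linear sequences the
  scans clip at the edges, and a trailing partial codon can still carry a
  `T`/`TA` incomplete-stop candidate.
* **Gene length unit** is nucleotides.  Reference CDS lengths are
  frequently not multiples of 3 precisely because of incomplete stops;
  nucleotides are the only unit under which reference lengths and
  candidate lengths 3(e−s)+offset are commensurable.
* **Ties** are broken deterministically: longer gene, then start closer
  to the hit start, then the most upstream start.  Identical inputs give
  byte-identical outputs.
* **Ambiguity codes.**  Codons containing `N` (or other IUPAC wildcards)
  translate to an unknown outcome: they are never treated as stop codons
  and never become candidates, avoiding spurious terminations at
  low-quality positions.
* **λ denominators** follow the estimator literally: a species whose gene
  length equals l is counted in both L≤ and L≥, so the denominator may
  exceed the species count and λ(median) can reach exactly 1.
* **Per-species length values**: when a reference species carries
  multiple copies of a gene, the longest is kept — the distribution is a
  per-species statistic.
* **Stop-frequency floor**: the 0.01 floor is applied to start codons
  only; stop codons are filtered solely by the internal-codon criterion
  (a configurable `stop_min_freq` exists and defaults to 0).
* **Frequency denominators** are per (code table, gene), not pooled
  across genes: codon usage differs strongly between the 13 PCGs, which
  is the point of fitting them separately.
* **Code table 24**: implemented as defined in the NCBI registry
  (including the ATK initiation box).  Empirical usage that contradicts
  the registry's definitions — a documented phenomenon — is the business
  of the fitted usage tables, not of the static code tables.

## What the synthetic generator emulates

`simulate_reference_set()` produces genomes with the statistical
structure the predictor consumes: per-gene categorical start/stop codon
distributions (including incomplete stops), per-gene length variation
across species, AT-rich internal composition rejection-sampled to be free
of in-frame full stops, tRNA loci interleaved between genes in the manner
of the tRNA punctuation arrangement, and both strands represented.
`simulate_hits()` adds the homology-search bias: hits truncated uniformly
by up to `shrink_max` codons at either end, with query-model coordinates
set consistently.  One seed drives everything through deterministic
per-species substreams (so a test set can extend a training set without
duplicating species); sampling internal codons directly from the
stop-excluded conditional distribution implements the rejection step in
one draw.

What it does *not* emulate: sequence evolution (no substitution model, no
phylogeny), compositional strand asymmetry, overlapping genes, or
annotation errors in the reference.  Green tests on synthetic data
therefore demonstrate that the estimator and predictor are implemented
correctly and recover known parameters — not that real RefSeq-scale
accuracy is reproduced, which would require the real reference corpus.

### Generator defaults

The defaults model a vertebrate-like (code table 2) reference set:
start codons ATG 0.70, ATA 0.12, ATT 0.06, ATC 0.03, GTG 0.05, TTG 0.04
(restricted to the table's canonical set and renormalized); stop codons
TAA 0.40, TAG 0.15, AGA 0.10, AGG 0.03 plus incomplete stops TA 0.10 and
T 0.22 (T observed more often than TA); gene length means at typical
metazoan values (e.g. cox1 ≈ 1545 nt, nad3 ≈ 348 nt) with a standard
deviation of 4% of the mean; base composition A 0.32, C 0.22, G 0.13,
T 0.33; a tRNA locus of 70 nt between consecutive genes with probability
0.8; spacers up to 5 nt; 15% of genes on the minus strand; hit shrink
uniform on 0–10 codons.

## Test problem sizes and the recovery experiment

The checked properties run at deliberately modest sizes: oracle
equivalence compares the predictor against an independent exhaustive
scorer on 200 two-gene genomes of ≤ 2 kb; the δ properties are verified
on 10⁴ random hits; λ is compared against brute-force counting over
every length in the observed range of randomized multisets.

The parameter-recovery experiment trains on 500 simulated species and
tests on 100 fresh ones, requiring ≥ 90% exact recovery of both
boundaries.  Its conditions are a canonical-codon, vertebrate-like
regime: ATG-dominated starts (ATG 0.85, ATA 0.05, ATT 0.03, ATC 0.02,
GTG 0.05), full stops only (TAA 0.60, TAG 0.25, AGA 0.12, AGG 0.03), and
a tight per-gene length spread (sd 6 nt).  The tight spread is a
deliberate identifiability choice, not a convenience: λ is a two-sided
p-value, so for a species whose gene length falls in the tail of a wide
length distribution *any* chance start codon on the median-ward side of
the true start scores a higher λ and can legitimately win — under a
spread of 4% of gene length, exact-start recovery is intrinsically
bounded near 75% no matter how well the statistics are estimated.  A
recovery test must run where the truth is identifiable; the mixed wide
regime remains the generator default and is exercised by the oracle
equivalence and distribution-recovery tests instead.  The same
experiment also checks the directional claim about the legacy baseline:
with true starts placed more than 6 codons outside the shrunken hits
(shrink 7–10), the fixed ±6-codon window recovers strictly fewer
boundaries than the probabilistic method.

## Evaluation conventions

Predicted and reference genes pair by bidirectional largest overlap
within the same (genome, gene, strand); the signed boundary difference is
positive when the prediction lies outside the reference gene, computed
strand-aware, with the shorter arc used on circular genomes when the
length is known.  Summaries report mean and standard deviation
(population convention — the divisor is N) of the absolute differences
per boundary, and the fraction of genes whose *maximum* absolute
start/stop difference is at most 0, 3, 9 and 30 bp.  Incomplete stops
are annotated at their last covered position, so comparisons against
references that annotate a projected full codon will show 1–2 bp
differences by construction.

## Known limitations

* Out-of-frame starts (such as the *Drosophila* cox1 AUAA quadruplet)
  are deliberately out of scope: admitting them would multiply the
  candidate space without a usable model of the frameshift mechanism.
* The method is reference-bound: codons never annotated in the training
  set have φ = 0 and can only be reached through the fallback.
* The free-text exception notes of the NCBI code-table pages
  (lineage-specific reassignments) are not modeled.
* GenBank flat-file parsing covers the 5-column feature-table subset
  (spans, gene symbols, transl_table) rather than the full format.
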