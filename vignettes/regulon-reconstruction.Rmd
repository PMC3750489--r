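---
title: "Comparative-genomics reconstruction of sugar-utilization regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative-genomics reconstruction of sugar-utilization regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(togaregulon)
```

## The problem and the procedure

Bacterial transcription factors (TFs) that control carbohydrate
utilization typically bind short, partially degenerate DNA sites upstream
of the operons they regulate. When a group of related genomes is
available, a regulon — the set of operons controlled by one TF — can be
reconstructed without any binding data by exploiting two regularities:
sugar TFs tend to be encoded inside the gene clusters they control
(autoregulation), and true binding sites are conserved upstream of
orthologous operons while spurious matches are not.

`togaregulon` implements that procedure as a pipeline of small, testable
steps:

1. **Training set.** For a TF ortholog group, collect the upstream regions
   of all operons within a fixed gene-neighbourhood radius of the TF gene
   in every genome carrying it (`neighborhood_training_set()`). Operons
   are predicted by chaining same-strand neighbours with intergenic gaps
   of at most `max_gap` nt (`predict_operons()`).
2. **Motif discovery.** A Gibbs site sampler (`discover_profile()`) finds
   the shared motif in the training regions and returns a positional
   count/weight profile (`build_pwm()`).
3. **Scoring and threshold.** A candidate site's score is the sum of
   positional nucleotide weights,
   \(w(b,i) = \log_2\frac{n(b,i)+p}{(N+4p)\,q(b)}\) with pseudocount
   \(p\) against background \(q\) (`score_site()`). The score threshold is
   the *lowest score observed in the training set* (`set_threshold()`), so
   every training site passes by construction.
4. **Propagation and conservation filter.** The profile scans every
   operon's upstream region in every genome (`scan_genome()`); hits are
   grouped by the target's ortholog group, and an interaction is accepted
   only when supported in at least `k_min` genomes that carry the TF
   (`propagate()`, `consistency_filter()`). Genomes lacking the TF never
   block acceptance elsewhere.
5. **Iterative refinement.** Accepted sites are added to the training set,
   the profile rebuilt, and the threshold reset to the new training
   minimum, until the accepted site set stops changing
   (`iterate_refinement()`).
6. **Expression concordance.** Reconstructed regulons are compared with a
   normalized log2 expression matrix: fold change of each sugar condition
   against a reference sugar, a strict `FC > 2` induction rule, and an
   upper-tail hypergeometric enrichment with Benjamini–Hochberg
   correction across the regulons tested (`fold_change()`,
   `classify_induction()`, `enrich_regulons()`).

The packaged catalog (`load_fixture_catalog()`) carries the *T. maritima*
inventory — pathway rows, regulon/operon/gene lists, per-promoter site
records, the TF presence matrix over 11 Thermotogales genomes — and
`catalog_counts()` / `check_consistency()` recompute its bookkeeping
totals from the row-level data rather than trusting any printed sum.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| upstream window | 300 + 20 | nt | typical span of bacterial regulatory regions plus a short stretch past the start codon; promoter-proximal sites stay inside it |
| `max_gap` (operon chaining) | 100 | nt | common bacterial operon heuristic; published regulon-reconstruction workflows rarely state one |
| minimum region length | 30 | nt | shorter truncated regions carry no usable signal and are skipped with a warning |
| motif width `L` | caller-set (17 for the pectin-regulator benchmark) | nt | width is an input, not auto-selected |
| pseudocount `p` | 0.25 | counts/base | keeps log-odds finite for unseen bases without flattening small training sets |
| background `q` | uniform | — | synthetic benchmarks are near-uniform; for real genomes pass the genome-wide mononucleotide frequencies |
| `n_restarts` | 20 | — | the sampler is multimodal; restarts are the robustness lever |
| `gamma` (zoops site prior) | 0.5 | — | a region opts out unless a window beats `log2(2m(1-γ)/γ)`, the log-odds a best-of-`m`-windows background match would warrant |
| `k_min` | 2 if ≤4 TF genomes, else 3 | genomes | "conserved" is qualitative in the field; the default is logged and configurable |
| induction rule | FC > 2 (strict) | linear fold change | FC = 2.0 exactly is *not* induced |
| BH cutoff | q = 0.05 | — | the concordance statistic is tested across ~tens of regulons in one run |

## Design choices made where the design was open

- **Coordinates are 1-based inclusive everywhere** (GFF3 convention),
  including site offsets within regions. R's sequence ecosystem is
  1-based; carrying a second internal convention plus converters would
  add bug surface without benefit. Hit tables report both the region
  offset and the genomic position of each site.
- **Discovery objective and mode.** The one-per-region objective is the
  total information content of the aligned sites; ties between restarts
  keep the first (lowest-index) optimum, making results reproducible for
  a given seed. Because not every neighbourhood operon is regulated, the
  pipeline wrapper (`reconstruct_regulon()`) uses the zero-or-one
  occurrence mode by default, with the penalized objective
  \(\sum_i (s_i - \text{null}_i)\) over retained sites.
- **Sampler robustness.** Each restart is seeded by *site projection from
  an over-represented word*: occurrences of the most repeated 8-mers
  (canonicalized over strands) across the training regions are candidate
  starting windows, every region is aligned to the chosen window
  greedily, and annealing proceeds from there. Whole-alignment
  phase-shift moves (±1–3 columns) run during and after annealing to
  escape shifted optima. Restart `r` consumes its own derived seed, so
  increasing `n_restarts` can only improve the reported optimum.
- **Shared divergent regions.** Two operons transcribed apart from a
  common intergenic segment both receive that segment as upstream region
  and cross-reference each other. For *discovery* the training set keeps
  only one member of each pair — the duplicated segment would otherwise
  masquerade as a perfectly conserved motif. For *scanning*, both operons
  are scanned and a shared passing site assigns both (both strands are
  scored, so passing is orientation-agnostic); the conservation filter
  removes partners that are not supported across genomes.
- **One best site per operon** enters a regulon; all overlapping hits are
  reported by the scanner and deduplication is deliberately a
  regulon-level concern. Dual regulation of one promoter by two TFs is
  modelled as two independent profiles hitting the same region, never
  merged.
- **Refinement fixed point.** The loop stops when the accepted site set
  repeats *or* the training set is unchanged (the rebuilt profile and
  threshold are then identical, so the next scan must repeat); original
  training sites are never dropped. Oscillation past `max_iter` returns
  the last model with a warning rather than failing.
- **Effectors are metadata.** Sugar-effector assignments are carried from
  configuration/fixtures and never inferred.
- **Fixture conventions.** Gene lists in the packaged catalog use
  published gene names where the text enumerates them and neutral
  locus-tag placeholders elsewhere; the consistency checks compare
  *counts*, which are fully transcribed, not gene identities. Site
  records count each TF's site once at dual-regulated promoters. Two
  printed table totals are not reproducible from the printed rows (the
  enzyme column sums to 126 vs the printed 127, the gene total to 240 vs
  241); `check_consistency()` flags exactly these as
  `EXPECTED-MISMATCH`.

## What the synthetic generator emulates — and what it does not

`generate_community()` builds several single-contig genomes sharing
ortholog groups. Each regulon is a TF group plus target groups laid out
as a contiguous cluster (TF inside it, emulating TFs encoded within their
regulated loci) in the genomes that carry it; one site sampled
column-wise from a ground-truth PWM (`sample_pwm()`, per-column
information content solved to the target; default 1.2 bits/column) is
planted in each regulated gene's upstream intergenic segment at a
uniform-random offset. Background sequence is i.i.d. at 46% GC
(approximately the *T. maritima* genomic composition); genes are spaced
by 250-nt intergenic segments, so every gene forms its own operon under
the default chaining rule and truth tables can name operons directly.
Genomes outside a regulon's subset keep the target genes but lose the TF
gene (ortholog loss). One master seed drives named streams per artifact,
so outputs are byte-identical given the seed and stages can be
regenerated independently.

`generate_expression()` emulates the sugar-panel design: per-gene
baselines `N(8, 1)` on the log2 scale, a gene-specific true effect
`N(mu_log2fc, sigma)` added on the regulon's cognate condition (defaults
4 and 0.3), independent replicate noise (sd 0.15), two replicates, and an
unshifted reference condition. Probes can be removed to emulate platform
gaps; missing genes are surfaced per regulon, never imputed.

Deliberately absent from the generator: phylogenetic correlation between
genomes, repeats and compositional heterogeneity, indels in motif
instances, horizontal transfer, multi-gene operons in the planted
clusters, and read-through/terminator structure. Passing the synthetic
benchmarks therefore demonstrates that the inference machinery is
correct and well-calibrated under the stated statistical model — not
that real genomes, whose backgrounds are repeat-rich and phylogenetically
structured, would yield the same accuracy.

## Numerical choices and degenerate inputs

- Scores are exact floats internally; hit tables print 4 decimals.
  Threshold comparisons use `score >= T` with a 1e-12 guard so training
  sites pass under floating-point reassociation.
- Regions shorter than `L` are skipped with a message; an all-short
  training set is an error. Operons at contig edges yield truncated
  regions, not errors. A window specification with a non-positive part
  is an error.
- Ambiguity codes are rejected: profiles and scores are defined over
  A/C/G/T only.
- Palindromic profiles symmetrize counts by averaging with the
  reverse-complement mirror; +/− hits at one offset then score equally
  and are collapsed to a single "+" record.
- In `sample_pwm()` the middle column of an odd-width palindrome must be
  its own complement, which caps its information content below 1 bit;
  the per-column target is reduced accordingly for that column only.

## Problem sizes used by the tests and the acceptance script

The packaged benchmarks run at desk scale, chosen as the smallest sizes
at which the statistical claims are stable: planted-motif recovery uses
10 regions x 240 nt with a 17-nt motif over 20 seeds; end-to-end
recovery uses 5 genomes x 40 ortholog groups with 3 regulons x 6 operons
planted in 4 genomes over 20 seeds (10 sampler restarts per regulon);
expression concordance uses 2 genomes x 30 groups with a 6-operon
regulon over 20 seeds. The fixture bookkeeping is exact and runs in
seconds.

## Known limitations

- The sampler assumes a fixed motif width; width selection is left to
  the caller (scan widths externally if needed).
- The background model is mononucleotide i.i.d.; dinucleotide or
  higher-order backgrounds are out of scope.
- PWM scores carry no p-value calibration — the minimum-training-score
  rule is a raw score cutoff by design, and an optional fractional
  threshold slack exists only for exploratory scans.
- The conservation filter uses one global threshold across genomes, with
  a per-genome override for users who prefer genome-specific cutoffs.
- Site-level bookkeeping in shared divergent regions reports the best
  site per operon; when one shared segment carries two planted sites the
  weaker one may be shadowed, which depresses site-level (not
  gene-level) recall on the synthetic benchmark.
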