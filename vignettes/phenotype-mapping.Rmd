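---
title: "Phenotype mapping of drug response networks: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype mapping of drug response networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmapr)
options(pmapr.verbose = FALSE)
```

## The model

`pmapr` treats a drug response phenotype as an emergent property of a gene
network rather than of single markers. The chain of inference is:

1. **Extreme-tail phenotyping.** Per (drug, group) condition, samples are
   ranked by EC50 and the k most sensitive / k most resistant form the two
   phenotype tails. k defaults to 15: with panels of 60–90 cell lines per
   group this captures the distribution's extremes while leaving the bulk
   unlabeled. Ranking ties are broken by lexicographic sample ID — the
   source procedure is silent on ties and determinism matters more than any
   particular choice. A sample may sit in tails of several drugs; the
   per-drug definitions are independent.
2. **Template matching.** A gene's differential expression is scored as the
   Pearson correlation between its expression across the 2k tail samples
   and the binary template (1 = sensitive tail, 0 = resistant). For a binary
   template with equal groups, r is a monotone transform of the two-group
   ANOVA F statistic, so this is the classic state-dependent "template
   matching" selection; we report the two-sided p from the t transform with
   2k − 2 df. On 8-sample toys this p tracks the exhaustive permutation p
   within the discreteness of a 70-assignment null (bounds frozen from a
   pre-build simulation; see `test-pdeg.R`).
3. **PDEG calling.** A gene joins the PDEG set of a phenotype class (drug
   class × response) iff it passes template matching in a member condition
   with the matching direction *and* is up-regulated in ≥ 2 distinct cell
   lines of that response across those conditions. "Up-regulated in a cell
   line" is not numerically defined in the source method; we operationalize
   it as a z-score > `up_z` (default 1.0) against all samples of the
   condition — scale-free and auditable. Only up-regulation defines PDEGs;
   there are no down-regulated PDEGs by construction.
4. **N1/N2 graph mining.** On the cleaned PPI graph (self-loops and
   duplicate edges removed), N1 = non-PDEG nodes with ≥ `min_links` PDEG
   neighbors, N2 = remaining nodes with ≥ 1 N1 neighbor and ≥ `min_links`
   PDEG neighbors, UBC excluded from N2 only (it is an extreme hub; it may
   still be N1 and carry a PF score). The source text says both "larger
   than two" and "at least two"; the definitional sentences dominate, so
   `min_links = 2` is the default and the stricter reading is one flag away.
   PDEGs are excluded from N1/N2 membership, and N1 status takes precedence
   over N2 so the role ledgers never double-count.
5. **Frequencies and PF scores.** The pair registry lists every (PDEG, N1)
   adjacency; its length M is the row count of the M × F matrix (F = 2: the
   N1 and N2 role columns). An N1 gene's frequency is its registry row
   count (hence ≥ min_links, and Σ freq = M). For N2 genes the source only
   says they "appear across M gene pairs"; we count gene g in row (p, n)
   iff g is adjacent to both p and n, which ties both columns to the same M
   rows; counting PDEG neighbors instead is available via
   `freq_mode = "pdeg_neighbors"`. PF = frequency in the sensitive network
   minus frequency in the resistant network, per role; tables report
   `pf_sum = pf_n1 + pf_n2`. GSEA ranks default to `pf_n1` (the stated
   ranking basis) with `pf_sum` available, since published summary tables
   report the N1 + N2 sum.

## Enrichment

* **ORA**: exact hypergeometric upper tail per pathway restricted to the
  gene universe; Bonferroni multiplies by the number of pathways actually
  tested (those with ≥ `min_genes` = 5 in-universe members), the
  conservative defensible reading of "pathways … were considered".
* **Pre-ranked GSEA**: weighted KS running sum (weight exponent default
  p = 1; the source does not state one, and p = 0 gives the unweighted
  classic statistic used in the closed-form tests). The null randomly swaps
  gene labels — the standard pre-ranked null and the only one available
  without sample-level data. `np` uses the +1 Monte-Carlo correction, so it
  is never exactly zero. When `choose(N, k)` is small and p = 0, an
  exhaustive mode enumerates every hit assignment for an exact permutation
  p; 56 random draws cannot reproduce an exhaustive 56-assignment null, so
  exactness requires enumeration.

## Knockdown consistency

The sign of `pf_sum` predicts directionality: negative (resistant-network
gene) ⇒ knockdown decreases sensitivity; positive ⇒ increases; zero ⇒ not
evaluable. Observed screens are classified per cell line; mixed per-drug
observations within one line follow the responsive drug(s). Full agreement
earns the magnitude band — weak |PF| < 10, moderate 10–100, strong > 100 —
with both boundaries assigned to the moderate band ("between 10 and 100"
read inclusively; no transcribed screen row contradicts this). Agreement in
a strict subset of lines keeps the band but is annotated as restricted;
no agreement, including all-non-responsive screens, is inconsistent.

## The synthetic world

`synth_config()` defaults state the emulated conditions, chosen once:

| parameter | default | why |
|---|---|---|
| drugs / groups | 4 drugs in 2 classes × 3 groups | the 24-condition design |
| `n_samples_per_condition` | 60 per group | panel scale that accommodates 15-sample tails with a free middle |
| `k` | 15 | the stated tail size |
| `pdeg_effect_size` | 2.0 log2 | a strong two-state signal |
| `noise_sd` | 0.5 log2 | typical array-scale residual noise |
| `n_genes` / `ppi_n_nodes` | 600 / 800 | desk-scale; PPI ⊃ expression namespace |
| `ppi_attachment` | 2 | Barabási–Albert heavy tail |
| `planted_n1_min_pdeg_links` | 3 | planted N1 clear the ≥2 rule with margin |
| dose grids | 0–2 µM and 0–5000 nM, 9 points × 3 wells | the stated assay design |

Baseline log2 expression is N(7, 1) per gene plus N(0, noise_sd) per value;
planted PDEGs gain `pdeg_effect_size` in every tail sample of their class.
Gaussian log2 noise is a stand-in — the source gives no noise model — and
the generator makes no attempt at probe effects, eQTL structure or
population-specific expression, so a green recovery test establishes
algorithmic correctness, not robustness to real microarray artifacts.

Two constructions make planted ground truth structural rather than
probabilistic: planted N1 genes are PPI-only nodes (absent from the
expression matrix, so they can never be called PDEGs and are always
disjoint from the planted PDEG sets), and background edges from a planted
N1 gene to opposite-response planted PDEGs of its drug class are removed,
so the planted PF sign cannot be flipped by preferential-attachment luck.
A pre-build Monte-Carlo oracle (1000 replicates) put per-condition recovery
of planted PDEGs at 1.00 under the default effect/noise/tails, so the ≥ 90%
end-to-end recall criterion is attainable in the stated world; the null
world (effect 0) calibrates to the nominal template-matching rate.

## Numerical choices

* **EC50 fitting**: 4PL least squares with log10(EC50) parameterization,
  5-point multi-start Nelder-Mead plus restarts (reltol 1e-15); EC50
  constrained to [min positive dose / 10, 10 × max dose]. The upper
  asymptote is free by default (`pin_upper` pins it at 1). Flat or
  increasing mean-response curves are flagged non-convergent and excluded
  downstream with a logged reason, not thrown. Noiseless curves are
  recovered to < 1e-6 relative error; with viability noise 0.05 the frozen
  Monte-Carlo bound is median |log10 ratio| < 0.05 (observed 0.035).
* **Determinism**: no RNG in the graph-mining module; all sets serialized
  lexicographically (radix sort, locale-independent); GSEA and the
  generator take explicit seeds; derived seeds stay below 2^31.
* **Duplicate expression rows** collapse by per-sample max (conservative
  for many-to-one probe maps; the source does not state its collapse rule);
  symbols are case-sensitive with no aliasing — silent aliasing is a known
  irreproducibility source. PSI-MI TAB identifier cells resolve by
  precedence gene symbol > locus tag > accession.
* **Perfect template matches** (|r| = 1) get the smallest positive double
  rather than p = 0, keeping p ∈ (0, 1].

## Known limitations

* The PPI network is unsigned; activation vs inhibition cannot be
  distinguished, which is the leading explanation for knockdown screens
  agreeing with the PF sign only about half the time. Signed-network
  reconstruction is out of scope.
* Hub genes are enriched among N1/N2 by connectivity alone; the per-DRN
  degree table is emitted precisely so users can audit hub-driven calls.
* Whether a gene's ≥ 2-cell-line evidence must come from conditions where
  it also passes template matching is ambiguous in the source; we require
  it (stricter). Evidence counts distinct cell lines, so one line in the
  tails of two drugs of a class contributes once.
* PDEG recall and PF sign guarantees hold in the synthetic world; on real
  data, symbol mismatches between expression and PPI namespaces are carried
  (and logged), not resolved.
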