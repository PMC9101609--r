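---
title: "Methods: from aberrant splice junctions to translation, decay and metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from aberrant splice junctions to translation, decay and metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Hotspot mutations in splicing factors such as SF3B1 cause the spliceosome to
select cryptic branchpoints, which activates cryptic 3′ splice sites located
upstream of the canonical acceptors. The resulting aberrant transcripts
retain a short intronic stretch ("insert"). What happens to these transcripts
— whether they are translated, degraded by nonsense-mediated decay (NMD), and
whether they change protein output and cell physiology — is the question this
package operationalizes. It provides a tested implementation of each analysis
step:

1. **Junction quantification** — aberrant vs canonical junction counts,
   normalization, the *aberrant splice index*, and differential junction
   usage between genotypes.
2. **Translation efficiency (TE)** — a polysome/monosome log-ratio per
   junction with an exact-test significance filter, classifying aberrant
   transcripts into *group A* (relatively more translated than their
   canonical counterpart) and *group B* (less translated).
3. **Splice annotation** — insert length, reading frame, premature
   termination codons (PTC), and predicted NMD sensitivity.
4. **Proteome integration** — label-free differential abundance with
   peptide-count filtering, condition-unique detection, and splice/proteome
   overlaps.
5. **Metabolic assays** — extracellular-flux respiration parameters, 4PL
   IC50 fitting, and percent-change statistics with the Mann–Whitney U test.

A synthetic-data generator plants known truth for every stage, so the whole
pipeline is testable end to end without access to any external dataset.

# Models and statistics

## Aberrant splice index and TE log-ratio

For a junction pair (aberrant $a$, canonical $c$) in genotype $g$ and
fraction pool $f$, with CPM-normalized counts $\tilde{x}$ averaged over
replicates, the splice index is $s_{gf} = \tilde{x}_{a,gf} /
\tilde{x}_{c,gf}$. The TE statistic contrasts the polysome and monosome
pools within one genotype:

$$\mathrm{TE} = \log_2 \frac{s_{g,\mathrm{poly}}}{s_{g,\mathrm{mono}}}
 = \log_2\frac{(\tilde{x}_a/\tilde{x}_c)_\mathrm{poly}}
              {(\tilde{x}_a/\tilde{x}_c)_\mathrm{mono}}.$$

A pseudocount of 0.5 is added to each of the four normalized means so the
statistic is finite at zero counts; 0.5 is the conventional half-count
continuity correction and its influence vanishes at realistic depths.
Because both junctions share each sample's size factor, the index and the TE
ratio are invariant to per-sample rescaling.

Significance uses a two-sided Fisher exact test on the 2×2 table
(aberrant, canonical) × (polysome, monosome) of pooled normalized counts,
rounded half-to-even to integers (exact tests require integer tables;
half-even rounding avoids systematic upward bias). The default threshold is
$p \le 10^{-5}$, the stringency conventionally applied to this filter;
junctions passing it are labeled A if TE > 0 and B if TE < 0, and group
percentages are computed over classified junctions only (so
pctA + pctB = 100 exactly). The same Fisher-on-pooled-counts construction,
with Benjamini–Hochberg adjustment, drives the genotype contrast in
`differential_junction_expression()`; an exact test was chosen because it is
correct at any count level and is checkable against an independent
hypergeometric enumeration oracle, which the test suite does for thousands
of tables.

## Frame, PTC and the 50-nt NMD rule

The insert length $d$ is the strand-aware distance between the cryptic and
canonical 3′ splice sites. A junction is *out-of-frame* iff
$d \bmod 3 \ne 0$. `scan_ptc()` reconstructs the aberrant isoform from the
genome and transcript model, translates codon-by-codon from the annotated
start in the (possibly shifted) frame, and reports the first stop codon that
precedes the position where the canonical stop would end. Frame and PTC are
reported as separate attributes: an in-frame insert can still carry an
in-frame stop.

NMD sensitivity follows the classical exon-junction-complex boundary rule: a
transcript is predicted NMD-sensitive iff it has a PTC located more than
50 nt upstream of its last exon–exon junction. The distance is measured from
the first nucleotide of the stop codon; the threshold is exposed as
`rule_nt = 50`. Single-exon transcripts are never NMD-sensitive under this
rule.

## Proteome differential abundance

Proteins are *quantified* when every replicate of both conditions has ≥ 3
peptides; *condition-unique* when fully detected (≥ 3 peptides everywhere)
in exactly one condition and absent (0 peptides) in the other. For
quantified proteins the fold change is the ratio of mean raw intensities
(MUT/WT) and the p-value a Welch t-test on log2 intensities, BH-adjusted
across quantified proteins. Calls require |FC| ≥ 1.2 and adjusted
p ≤ 0.05 by default; a `use_adjusted = FALSE` switch reproduces analyses
that filter on the raw p-value, a discrepancy that occurs between methods
sections and figure captions in practice.

Overlap percentages are printed to one decimal. Published reports are not
internally consistent about the rounding convention (the same article can
print one fraction truncated and another rounded), so `percent_of()` exposes
both `half_even` and `truncate`; the default is `half_even`.

## Respiration parameters

With segment levels $L_0$ (baseline), $L_1$ (post-oligomycin), $L_2$
(post-FCCP), $L_3$ (post-rotenone/antimycin A):
non-mitochondrial $= L_3$; basal $= L_0 - L_3$; ATP-linked $= L_0 - L_1$;
proton leak $=$ basal $-$ ATP-linked; maximal $= L_2 - L_3$; reserve $=$
maximal $-$ basal. The additivity identities hold exactly by construction on
every output. Segment level defaults to the segment mean; `baseline =
"first"` reproduces protocols that define basal respiration from the first
measurement. "Minimal/maximal" rates are implemented as the extreme segment
means — a documented convention, since "minimal" has no standard definition.

## Dose-response (4PL) fitting

Viability follows
$v(d) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) /
(1 + (d/\mathrm{IC}_{50})^{h})$, fitted by Levenberg–Marquardt
(`minpack.lm::nlsLM`) with a 15-point multistart grid (Hill slopes 0.5–3 ×
IC50 at the quartiles of the nonzero doses), the IC50 parameterized on the
log scale, and box constraints bottom ∈ [0, 1], top ∈ [0.5, 1.5]
appropriate for control-normalized viabilities. Dose 0 enters the model
exactly ($0^h = 0$), anchoring the untreated wells on the top asymptote;
mapping zero doses to a small positive value instead would bias the
noiseless fit by ~0.2%, which is why it was rejected. Flat curves
(top ≈ bottom) are flagged unidentifiable rather than fitted. The fit is
scale-equivariant: doses in nM recover 1000× the µM IC50.

## Percent changes

`percent_change()` reports $100\,(\bar{t} - \bar{c})/\bar{c}$ with the sign
convention of the stated direction, and a two-sided Mann–Whitney U p-value
(exact for small samples without ties; at n = 3 vs 3 the smallest achievable
two-sided p is 0.1). Glucose uptake is first normalized per cell.

# The synthetic-data generator

The generator emulates an isogenic mutant-vs-wild-type polysome-profiling
experiment at the study's stated conditions and is itself first-class,
tested code:

* **Gene models**: three-exon transcripts (exons 90–150 nt, introns
  49–179 nt) on one contig per gene, both strands, 12-nt 5′ UTR, CDS built
  from non-stop codons with a single terminal stop. Each first intron
  carries a cryptic 3′ss 9–59 nt upstream of the canonical acceptor. The
  out-of-frame share of insert lengths defaults to 69/113 ≈ 0.61, the
  composition observed for protein-changing junctions; every frameshifting
  insert carries a planted stop in the shifted frame, and 30% of in-frame
  inserts carry a planted in-frame stop so both NMD categories are
  populated.
* **Counts**: negative binomial (dispersion 0.05) around log-normal
  per-gene expression weights, two replicates per genotype × pool (the
  study design sequenced two), library size `depth` per sample. Cryptic
  usage is leaky in wild type (5% of canonical — splice indices are
  observed to be nonzero in wild-type cells) and 30% in the mutant.
  The planted TE shift (±1 log2 by default) is split symmetrically between
  pools; 35% of aberrant junctions get the positive shift (group A).
* **Proteome**: log-normal intensities (replicate SD 0.05 on the natural
  log scale, typical of well-behaved label-free triplicates); aberrantly
  spliced genes with NMD-sensitive junctions receive a planted 1/1.5
  down-fold with probability `proteome_link_prob`; 5% of proteins are
  planted to fail the peptide filter and 2% to be condition-unique.
* **Assays**: plateau-plus-Gaussian-noise OCR traces and 4PL viability
  curves with planted parameters.

All generators are pure functions of their configuration: each derives its
own RNG sub-stream from the master seed by a fixed offset, so adding a
generator never shifts another's draws, and identical configurations give
bit-identical outputs.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: alternative splicing beyond one cryptic acceptor
per gene, positional read bias and mappability, fraction-to-fraction
gradient chemistry, shared-peptide protein inference, batch effects, and
any dependence between junction usage and expression level. Recovery of the
planted 35% group-A share demonstrates that the estimator is unbiased under
the stated noise model, not that any particular biological dataset has that
composition.

# Numerical choices and degenerate inputs

* Counts are CPM-normalized; all-zero samples are an error, zeros stay
  zeros, and a splice index with a zero canonical count is flagged
  undefined rather than propagated as NaN.
* A TE-significant junction with log-ratio exactly 0 stays unclassified
  (flagged); classification is invariant to junction order.
* Fisher tables are rounded half-to-even; BH adjustment runs across the
  tested family only (junctions, or quantified proteins).
* Zero protein intensities are lifted by half the smallest positive
  intensity and flagged.
* Negative ATP-linked or reserve respiration is reported with a
  data-quality warning, not censored.
* The demo pipeline (`run_pipeline()`) simulates 150 genes at depth 3×10⁵
  and runs in seconds; the recovery analyses in the acceptance script use
  1000 genes at depth 2×10⁶ over 20 seeds, sizes at which the binomial
  standard error of a 35% share (≈1.5 points per seed) makes a ±3-point
  check meaningful.

# Worked example

```{r, eval = FALSE}
library(splicefate)

cfg <- sim_config(seed = 1, n_genes = 300, depth = 1e6)
ann <- make_annotation(cfg)
sim <- simulate_fraction_counts(cfg, ann)

te <- classify_groups(te_table(normalize_counts(sim$matrix)))
group_fractions(te)

paths <- write_annotation(ann, "annotation")
models <- read_annotation(paths[["bed"]], paths[["genome"]])
fp <- annotate_junctions(ann$junctions,
                         models[grepl("canonical", names(models))],
                         Biostrings::readDNAStringSet(paths[["genome"]]))
table(fp$frame, fp$nmd)

pr <- simulate_proteome(cfg, sim$truth)
dp <- differential_abundance(pr$quant)
overlap_splice_protein(sim$truth$gene_id[sim$truth$aberrant], dp)
```

# Known limitations

* The TE exact test treats pooled counts as independent draws; replicate
  overdispersion beyond the pooled table is not modeled, so at very deep
  libraries the p-values are anti-conservative relative to a
  replicate-aware model. The planted-truth recovery tests quantify the
  practical effect (sign misclassification ≈ 1–2% at the default
  dispersion).
* NMD prediction implements only the 50-nt boundary rule; long 3′ UTRs,
  uORFs and other determinants are out of scope.
* The proteome model plants fold changes at the protein level; peptide-level
  inference and shared peptides are not simulated.
* `fit_4pl()` assumes viabilities normalized to an untreated control; data
  on other scales must be rescaled first.
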