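---
title: "Methods and design of ribopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ribopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ribopes)
```

# Scope

`ribopes` re-implements, as one tested pipeline, three computational arms
of a tRNA-fragment translational-control study:

1. **Translatome analysis** — ribosome-profiling quality control (P-site
   offsets, trinucleotide periodicity, region RPKM, codon occupancy),
   translation-efficiency (TE) computation, and differential-translation
   calling, followed by 5′ TOP/PES motif classification and
   hypergeometric enrichment among up-translated transcripts.
2. **HDX-MS differential uptake** — per-peptide deuterium uptake,
   apo-vs-ligand differences with a ±0.5 Da significance criterion, and
   residue-level protection maps.
3. **Equilibrium binding** — one-site Kd fitting of fraction-bound
   titrations with a no-binding verdict for flat curves.

Every input class can be generated by seeded simulators with planted
ground truth, so each analysis is testable by parameter recovery rather
than only by example.

# Coordinate conventions

All ribosome-profiling computation happens in transcript space with
0-based half-open coordinates: the 5′ UTR is `[0, cds_start)`, the CDS
`[cds_start, cds_end)`, the 3′ UTR `[cds_end, length)`. Annotation ingest
(`read_transcript_bed()`, `read_transcript_gtf()`) converts 1-based GTF
and 0-based BED genome coordinates and resolves strand, so everything
downstream is strand-free. One transcript per gene is required, matching
the custom annotation style the analysis assumes.

# Ribosome profiling

## P-site offsets

For each read length $L$, the offset is the modal distance from a
footprint's 5′ end to the annotated start codon over reads whose 5′ ends
fall in the metagene window $[\mathrm{cds\_start}-30, \mathrm{cds\_start})$.
Initiating ribosomes pile up with their P-site on the start codon, so
this mode is the 5′-end→P-site distance for that length. Ties break
toward the smaller offset; lengths with fewer than 50 window reads (both
defaults configurable) inherit the pooled-signal mode. The method is
deliberately simple and fully specified, since published offset tools do
not document a single canonical algorithm; recovery is exact on
noiseless simulations for every represented read length.

The count simulator therefore includes a `start_codon_weight`
(default 5×) initiation pileup. Without it, uniform P-site placement over
codons makes the window candidates $\{o, o-3, o-6, \dots\}$
equiprobable, and no mode-based estimator can identify the true offset
$o$ — the pileup is a genuine feature of footprint libraries, not a
convenience.

## Periodicity, regions, occupancy

P-site frame fractions are computed over CDS-internal P-sites only;
region percentages over all P-sites in the transcript. RPKM is
`count / (region_kb × library_millions)`, with footprints assigned by
P-site and RNA fragments by 5′ end; zero-length regions report `NA`
rather than dividing by zero. Codon occupancy at the E/P/A site shifts
the assignment by −3/0/+3 nt, restricted to the CDS, and normalizes
per-codon site counts by codon usage across the analyzed CDSs, rescaled
to mean 1. Accepted read lengths default to the simulator's 26–32 nt
distribution.

# Translation efficiency and differential translation

TE is the ratio of footprint density over the CDS to mRNA density over
the exons, computed on replicate-pooled counts (library totals summed);
per-replicate TEs are kept in an attribute for diagnostics. When any of
a transcript's four pooled counts is below `min_counts` (10), a
symmetric pseudocount of 0.5 is added to all four before RPKM so fold
changes stay finite without biasing either condition.

Calls use strict inequalities exactly as the thresholds state:
up-translated iff `log2fc_te > 1`, `|log2fc_mrna| < 1` and footprint FDR
`< 0.2`; transcripts with `|log2fc_mrna| ≥ 1` are excluded as
transcriptional movers. The per-transcript footprint p-value is a
two-sided Fisher exact test of pooled CDS counts against library totals,
computed by exact hypergeometric enumeration (conditioning on margins
and summing all outcomes no more probable than observed) and
BH-adjusted. This test was a design choice — the source analysis names
its FDR but not its test — picked because it is exact, assumption-free,
and appropriate for duplicate libraries pooled by summation; it is
validated against `stats::fisher.test` in the test suite. The FDR is
computed on footprint counts (not a TE statistic), the literal reading
of "FDR of ribosome-protected fragments".

Global TE shifts between conditions are summarized by a two-sided
Wilcoxon signed-rank test on paired `log2(TE)` with the median shift.

# 5′ TOP / PES classification and enrichment

The operational motif rule (the source work does not formalize one): a
transcript carries a 5′ PES when a run of ≥ `min_run` (5) consecutive
pyrimidines begins within the first `window` (10) nt of the 5′ UTR; it
is a TOP when additionally the first transcribed nucleotide is C and the
run starts at position 1. Both knobs are arguments so alternative
definitions can be scored; U and T are equivalent throughout. TOP ⊆ PES
by construction.

Enrichment among up-translated transcripts is an exact upper-tail
hypergeometric test. The population is the set of transcripts passing
the coverage filter (not the whole annotation), which conditions the
test on what was actually testable.

# HDX-MS differential uptake

Uptake is the centroid mass difference from the undeuterated control,
`D(t) = centroid(t) − centroid(0)`, with no back-exchange correction;
normalization to full deuteration divides by
`max_exchangeable × d2o_fraction × recovery`, with recovery defaulting
to 80%. `max_exchangeable` excludes the two N-terminal residues and
prolines from position 3 on. Ingest keeps high- and medium-confidence
peptides and collapses duplicate peptide entries within a ±0.5 min
retention-time window.

Differences (ligand − apo) are computed per timepoint and for the
maximum uptake across timepoints, each called protected/exposed/ns at a
symmetric ±0.5 Da threshold; both surfaces are reported because the
upstream tooling's choice between them is unpublished. Residue-level
maps give each exchange-competent residue the unweighted mean of the
differences of covering peptides, then apply a 5-residue centered moving
average ("heavy smoothing"; window configurable, 1 disables, partial
windows at the edges of covered runs). Prolines and uncovered residues
stay `NA`.

Two consequences of this aggregation are worth knowing when reading the
maps, and they drive how the acceptance checks are measured:

* **Localization** is assessed on the maximum-uptake difference surface
  (the heat-map quantity). Per-timepoint surfaces can carry multi-Da
  peptide differences across a footprint boundary — a peptide straddling
  the edge donates its whole difference to all its competent residues —
  so protected calls can appear up to roughly a peptide length outside a
  true footprint. That is the peptide-overlap resolution limit inherent
  to bottom-up HDX, not an artifact of this implementation.
* **Detection** uses all surfaces: residues with fast intrinsic exchange
  saturate in both states before the last labelling time and lose their
  maximum-uptake contrast, but show clear protection at early
  timepoints. A footprint residue counts as detected when any timepoint
  surface calls it protected, which is how a time-resolved difference
  heat map is read in practice.

# Binding curves

`fit_kd()` fits the one-site hyperbola `f(C) = C/(Kd + C)` by
least squares (Levenberg–Marquardt, multi-start over log-spaced initial
Kd spanning the concentration range), with the ceiling fixed at 1
because fraction bound is already a ratio, and an optional fixed Hill
exponent. A fit must beat the flat model in an F-test at α = 0.05;
otherwise the verdict is `no_binding` with `kd = NA` — the behaviour
expected for scrambled-oligo controls. The fit is invariant to point
order and rescales exactly with concentration units.

# Synthetic data: what it emulates, and what it does not

All simulator distributions are package choices — the source study
provides no generative model — and their defaults are fixed once:

* **Transcriptome**: one transcript per gene; UTR5 20–200 nt, CDS
  100–500 codons (ATG + sense codons + stop, base composition tracking
  `gc_background` = 0.5), UTR3 50–400 nt; 15% of transcripts carry a
  planted PES (half of them TOP), rejection-sampled until the classifier
  reproduces the intended class, so truth tables agree with the
  classifier exactly.
* **Counts**: lognormal abundance (meanlog 3, sdlog 1.2) and baseline TE
  (meanlog 0, sdlog 0.5); a 4× TE effect on PES transcripts in the
  perturbed condition; read lengths 26–32 nt peaked at 28–29 with
  offsets 11–14; 85% frame-0 P-sites; 5× initiation dwell; two
  replicates of 2×10⁶ reads per library. Expected footprint counts are
  proportional to abundance × TE (the literal generative contract), so
  measured TE carries a per-transcript exon/CDS length factor that
  cancels from every fold change the pipeline thresholds on. RNA
  fragments are uniform over the transcript with no positional bias,
  since TE is a ratio.
* **HDX**: 636-residue random protein (5% proline); ~300 peptides sized
  to the observed map statistics (length 14.6 ± 7.9, redundancy 6.9);
  per-residue lognormal exchange rates (meanlog log(3×10⁻³) s⁻¹,
  sdlog 1.5, spanning the 30–9,000 s labelling series); a planted
  footprint at residues 180–290 slowing rates 5-fold; unimodal
  single-exponential kinetics summed over competent residues; Gaussian
  centroid noise per (peptide, time, state); D₂O fraction 0.83 and
  recovery 0.8.
* **Binding**: 12 log-spaced concentrations over 0.5–60 µM, true Kd
  2 µM, Gaussian noise (sd 0.02) on fraction bound, clipped to [0, 1].

Not emulated: sequencing errors and adapters, rRNA contamination, UMI
structure, isoform ambiguity, spectrum-level isotope envelopes, EX1/
bimodal exchange, gel densitometry. Passing recovery tests therefore
demonstrates correctness of the computations under clean generative
assumptions — not robustness to alignment artifacts or instrument drift.

One master seed expands into fixed per-stage substreams
(`substream_seed()`), so stages can be regenerated independently without
perturbing each other; identical seeds give byte-identical output files.

# Numerical and degenerate-input policy

Zero-length regions → `NA` RPKM; empty enrichment samples and zero
library totals are rejected with named errors; mode ties break toward
smaller offsets; all-zero paired TE differences give p = 1; negative
uptake is retained but flagged; peptide series without a t = 0 centroid
are dropped with a message; non-positive pulldown signals require an
explicit floor. BH-adjusted values are monotone, ≥ raw, capped at 1.

# Problem sizes used by tests and the acceptance script

Parameter-recovery runs use 1,000 transcripts, 15% PES, 4× TE effect,
duplicate libraries of 2×10⁶ reads, averaged over 10 seeds (null runs:
same conditions, effect 1×); QC recovery uses 300 transcripts at 10⁶
reads; HDX uses the full 636-residue default at zero centroid noise;
binding uses 100 noise seeds. Smaller sizes appear in unit tests where
a brute-force oracle must enumerate the same instance.

# Known limitations

* The TE model has no dispersion/GLM component; biological replicate
  variance beyond counting noise is out of scope by design.
* Residue-level HDX maps inherit peptide-length smearing (discussed
  above); interpret boundaries at peptide-overlap resolution.
* The motif rule is one documented operational definition of "PES";
  published analyses may have used another, which the `window`/`min_run`
  arguments can approximate.
* GTF ingest supports the one-transcript-per-gene annotations this
  pipeline targets, not general multi-isoform gene models.
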