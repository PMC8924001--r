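# ribopes

Small pseudouridylated tRNA fragments can rewire translation initiation:
they bind the poly(A)-binding protein, displace its translation-enhancer
partner, and preferentially dampen the translation of mRNAs that start
with a pyrimidine-enriched sequence (5′ PES, including classical 5′ TOP
motifs). Testing that model computationally takes three very different
analyses — a ribosome-profiling translatome comparison, an HDX-MS
protection map of the RNA–protein interface, and equilibrium
binding-curve fits — which are usually run through three unrelated
toolchains. `ribopes` implements all three as one tested R pipeline,
together with seeded simulators that generate every input class with
planted ground truth, so each analysis can be validated by parameter
recovery.

It is aimed at analysts who want a transparent, scriptable alternative
to the usual tool patchwork, and at methodologists who need a synthetic
testbed for TE calling or HDX difference mapping.

## What it computes

**Translatome.** Per-transcript translation efficiency
`TE = RPKM(CDS, footprints) / RPKM(exons, mRNA)`, on replicate-pooled
counts. Differential translation uses the cutoffs
`log2(FC TE KO/WT) > 1`, `|log2(FC mRNA)| < 1` and a footprint-count FDR
`< 0.2`, where the per-transcript p-value is a two-sided Fisher exact
test (exact hypergeometric enumeration) of pooled CDS counts against
library totals, BH-adjusted. Upstream QC re-implements metagene P-site
offset estimation (mode of 5′-end→start-codon distances per read
length), trinucleotide periodicity, region RPKM and E/P/A-site codon
occupancy. Downstream, 5′ UTRs are classified as TOP / PES / none (a
pyrimidine run ≥ 5 nt starting within 10 nt of the TSS; TOP = C-start
run at +1) and enrichment of PES among up-translated transcripts is an
exact upper-tail hypergeometric test.

**HDX-MS.** Deuterium uptake `D(t) = centroid(t) − centroid(0)` per
peptide and state (no back-exchange correction; normalization to 100%
D₂O with 80% recovery), apo-vs-ligand differences per timepoint and for
maximum uptake with a ±0.5 Da significance criterion, and residue-level
protection maps (unweighted mean over covering peptides, 5-residue
moving average, prolines uncoloured).

**Binding.** One-site fits `f(C) = C/(Kd + C)` with multi-start
Levenberg–Marquardt, standard errors from the fit, and a `no_binding`
verdict (Kd = NA) when the curve does not beat a flat model in an
F-test — the expected outcome for scrambled-oligo controls.

## Worked example

The bundled configuration simulates a complete study (300 transcripts,
15% with a planted PES, a 4× TE effect on PES transcripts in the
perturbed condition, duplicate libraries, one HDX experiment with a
protection footprint at residues 180–290, one binding titration) and
runs every stage:

```r
library(ribopes)

cfg <- read_run_config(overrides = list(
  seed = 7,
  transcriptome = list(n_transcripts = 300L),
  ribo = list(depth_rpf = 2e5, depth_rna = 2e5)))
res <- run_pipeline(cfg, "demo_run")
```

```
[simulate] 300 transcripts (37 PES, 17 TOP)
[simulate] 1218901 count records across 8 libraries
[riboqc] frame0 fraction 0.850, CDS P-sites 100.0%
[te] 300 transcripts, 37 up-translated
[enrich] k/n = 37/37 vs K/N = 37/300, p = 3.1e-48
[hdx] 295 peptides, redundancy 7.4, 92 residues protected
[binding] verdict binding, Kd = 1.982 uM
```

Reading the log: the QC stage recovers the simulated 85% frame-0
periodicity; the TE stage calls exactly the 37 transcripts carrying the
planted PES effect as up-translated; all 37 carry a PES against a
population share of 37/300, hence the extreme hypergeometric p; the HDX
stage maps a protected block inside the planted 180–290 footprint; and
the binding fit recovers the true Kd of 2 µM from a noisy titration:

```r
print(res$kd_fit)
#> Binding fit: Kd = 1.982 +- 0.057 (RSS 0.00321, n = 12)
print(res$hdx_qc)
#> HDX peptide map: 295 peptides, length 15.8 +- 7.3 aa,
#>   98.9% sequence coverage, redundancy 7.4
```

Artifacts (transcript FASTA/BED12, count TSVs, the TE table with its
thresholds manifest, UTR features, enrichment JSON, the residue-level
ΔD matrix, QC and fit reports, and an MD5 manifest) are written under
the output directory; rerunning with unchanged inputs skips
recomputation.

Individual stages are plain functions —
`estimate_psite_offsets()`, `quantify_regions()`, `compute_te()`,
`classify_translation()`, `classify_5prime_motif()`,
`hypergeometric_enrichment()`, `compute_uptake()`,
`residue_delta_map()`, `fit_kd()` — and accept data from files
(`read_transcript_gtf()`, `read_ribo_counts()`, `read_hdx_csv()`) as
readily as from the simulators.

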