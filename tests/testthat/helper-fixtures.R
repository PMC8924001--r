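## Shared fixtures and independent brute-force oracles used across tests.

library(data.table)

## Three hand-built toy transcripts with known segmentation.
toy_models <- function() {
  transcript_models(
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G2", "G3"),
    sequence = c(
      paste0("GGGAAAGGGG", "ATGAAACCCGGGTAA", "GGGGGAAA"),      # 10/15/8
      paste0(strrep("A", 20), "ATG", strrep("GCT", 40), "TGA",
             strrep("T", 30)),                                  # 20/126/30
      paste0(strrep("C", 15), "ATGTTTAAATAG")                   # 15/12/0
    ),
    cds_start = c(10L, 20L, 15L),
    cds_end = c(25L, 146L, 27L)
  )
}

## Build a ribo_profile from parallel vectors.
make_profile <- function(transcript_id, read_length, position, count,
                         library_total = sum(count)) {
  p <- data.table(transcript_id = transcript_id,
                  read_length = as.integer(read_length),
                  position = as.integer(position),
                  count = as.integer(count))
  setattr(p, "library_total", library_total)
  setattr(p, "class", c("ribo_profile", class(p)))
  p
}

## Build a region_quant table directly from counts (for translatome tests).
make_quant <- function(transcript_id, region, length, count,
                       library_total) {
  q <- data.table(transcript_id = transcript_id, region = region,
                  length = as.integer(length), count = as.numeric(count))
  q[, rpkm := count / (length / 1e3 * library_total / 1e6)]
  setattr(q, "library_total", library_total)
  setattr(q, "class", c("region_quant", class(q)))
  q
}

## Independent upper-tail hypergeometric oracle by combinatorial sum.
hyper_tail_oracle <- function(N, K, n, k) {
  js <- seq.int(k, min(K, n))
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Independent BH step-up oracle applied literally from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- prev
  }
  pmin(adj, 1)
}

## Independent per-position region recount oracle.
region_count_oracle <- function(profile, models, mode, offsets = NULL) {
  res <- list()
  for (i in seq_len(nrow(profile))) {
    row <- profile[i]
    mod <- models[transcript_id == row$transcript_id]
    pos <- row$position
    if (mode == "rpf_psite") {
      off <- offsets[read_length == row$read_length]$offset
      if (!length(off)) next
      pos <- pos + off
    }
    if (pos < 0 || pos >= mod$length) next
    reg <- if (pos < mod$cds_start) "utr5"
           else if (pos < mod$cds_end) "cds" else "utr3"
    for (r in c(reg, "exon")) {
      key <- paste(row$transcript_id, r)
      res[[key]] <- (res[[key]] %||% 0) + row$count
    }
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent residue-level aggregation oracle (unweighted mean over
## covering peptides' exchange-competent residues).
residue_map_oracle <- function(peps, deltas, protein_length) {
  out <- rep(NA_real_, protein_length)
  for (res in seq_len(protein_length)) {
    vals <- c()
    for (i in seq_len(nrow(peps))) {
      p <- peps[i]
      if (res < p$peptide_start + 2L || res > p$peptide_end) next
      aa <- substr(p$sequence, res - p$peptide_start + 1L,
                   res - p$peptide_start + 1L)
      if (aa == "P") next
      vals <- c(vals, deltas[i])
    }
    if (length(vals)) out[res] <- mean(vals)
  }
  out
}

## Standard simulated translatome run used by several tests.
run_translatome <- function(seed, n_transcripts = 1000L,
                            te_effect = 4, depth = 2e6,
                            pes_fraction = 0.15, replicates = 2L) {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = n_transcripts, pes_fraction = pes_fraction,
    seed = seed))
  sim <- simulate_ribo_counts(tx$models, tx$truth, sim_ribo_params(
    te_effect_on_pes = te_effect, depth_rpf = depth, depth_rna = depth,
    replicates = replicates, seed = seed))
  prof <- function(a, cond, r) get_profile(sim$counts, a, cond, r)
  reps <- seq_len(replicates)
  offsets <- estimate_psite_offsets(
    merge_profiles(c(lapply(reps, function(r) prof("rpf", "reference", r)),
                     lapply(reps, function(r) prof("rpf", "perturbed", r)))),
    tx$models)
  quant <- function(a, cond, mode)
    lapply(reps, function(r)
      quantify_regions(prof(a, cond, r), tx$models, mode, offsets))
  te <- compute_te(
    rpf_wt = quant("rpf", "reference", "rpf_psite"),
    rpf_ko = quant("rpf", "perturbed", "rpf_psite"),
    rna_wt = quant("rna", "reference", "rna_fragment"),
    rna_ko = quant("rna", "perturbed", "rna_fragment"))
  te <- classify_translation(te)
  list(tx = tx, sim = sim, te = te, offsets = offsets)
}
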