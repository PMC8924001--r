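#' Parameters for the synthetic transcriptome generator
#'
#' Defines the annotation the simulated study runs on: one transcript per
#' gene with a 5' UTR, an in-frame CDS (start codon, sense codons, stop
#' codon) and a 3' UTR. A configurable fraction of transcripts carries a
#' planted 5' pyrimidine-enriched sequence (PES) in the first nucleotides of
#' the 5' UTR; a sub-fraction of those is a canonical TOP (C at +1,
#' pyrimidine run from position 1).
#'
#' @param n_transcripts Number of transcripts (= genes).
#' @param utr5_length_range,utr3_length_range Integer ranges, nt.
#' @param cds_codons_range Integer range of CDS length in codons, including
#'   start and stop.
#' @param gc_background Background GC fraction of generated sequence.
#' @param pes_fraction Fraction of transcripts given a planted 5' PES.
#' @param top_fraction_of_pes Fraction of PES transcripts that are TOP.
#' @param pes_window,pes_min_run Motif rule the planting must satisfy; must
#'   match the settings used for downstream classification.
#' @param seed Master seed (expanded via [substream_seed()]).
#' @return A list of class `sim_transcriptome_params`.
#' @export
sim_transcriptome_params <- function(n_transcripts = 1000L,
                                     utr5_length_range = c(20L, 200L),
                                     cds_codons_range = c(100L, 500L),
                                     utr3_length_range = c(50L, 400L),
                                     gc_background = 0.5,
                                     pes_fraction = 0.15,
                                     top_fraction_of_pes = 0.5,
                                     pes_window = 10L,
                                     pes_min_run = 5L,
                                     seed = 1L) {
  stopifnot(n_transcripts >= 1L)
  check_range(utr5_length_range, "utr5_length_range")
  check_range(cds_codons_range, "cds_codons_range")
  check_range(utr3_length_range, "utr3_length_range")
  if (cds_codons_range[1] < 3L)
    stop("CDS must have at least 3 codons (start, one sense, stop)",
         call. = FALSE)
  check_fraction(gc_background, "gc_background")
  check_fraction(pes_fraction, "pes_fraction")
  check_fraction(top_fraction_of_pes, "top_fraction_of_pes")
  if (utr5_length_range[1] < pes_window + pes_min_run)
    stop("minimum 5' UTR length must be >= pes_window + pes_min_run ",
         "so planted motifs always fit", call. = FALSE)
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         utr5_length_range = as.integer(utr5_length_range),
         cds_codons_range = as.integer(cds_codons_range),
         utr3_length_range = as.integer(utr3_length_range),
         gc_background = gc_background,
         pes_fraction = pes_fraction,
         top_fraction_of_pes = top_fraction_of_pes,
         pes_window = as.integer(pes_window),
         pes_min_run = as.integer(pes_min_run),
         seed = as.integer(seed)),
    class = "sim_transcriptome_params"
  )
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_bases <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_probs(gc))
}

## All 61 sense codons with probabilities proportional to the product of
## background base probabilities, so CDS base composition tracks
## gc_background.
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

## Draw one 5' UTR whose classifier outcome equals `target`
## ("TOP", "PES_non_TOP" or "none"); rejection sampling guarantees the
## truth table matches the classifier exactly.
draw_utr5 <- function(len, target, gc, window, min_run) {
  repeat {
    s <- random_bases(len, gc)
    if (target != "none") {
      run_len <- sample(min_run:(min_run + 3L), 1L)
      start <- if (target == "TOP") 1L else sample(2:window, 1L)
      run <- sample(c("C", "T"), run_len, replace = TRUE)
      if (target == "TOP") run[1] <- "C"
      s[start:(start + run_len - 1L)] <- run
    }
    seq <- paste(s, collapse = "")
    if (classify_5prime_motif(seq, window, min_run) == target) return(seq)
  }
}

#' Simulate a transcriptome with planted 5' PES/TOP motifs
#'
#' Generates transcript models plus a truth table of planted motif classes.
#' PES status is drawn per transcript as Bernoulli(`pes_fraction`); planted
#' sequences are rejection-sampled until [classify_5prime_motif()] (at the
#' params' window and run settings) reproduces the intended class, so the
#' truth table agrees with the classifier by construction.
#'
#' @param params A [sim_transcriptome_params()] object.
#' @return A list with `models` (a `transcript_models` table) and `truth`
#'   (a `data.table` with `transcript_id`, `gene_id`, `pes_flag`,
#'   `motif_class`).
#' @export
simulate_transcriptome <- function(params) {
  stopifnot(inherits(params, "sim_transcriptome_params"))
  with_seed(substream_seed(params$seed, "transcriptome"), {
    n <- params$n_transcripts
    gc <- params$gc_background
    utr5_len <- sample_range(n, params$utr5_length_range)
    codons <- sample_range(n, params$cds_codons_range)
    utr3_len <- sample_range(n, params$utr3_length_range)

    pes <- rbinom(n, 1L, params$pes_fraction) == 1L
    top <- pes & rbinom(n, 1L, params$top_fraction_of_pes) == 1L
    target <- ifelse(top, "TOP", ifelse(pes, "PES_non_TOP", "none"))

    utr5 <- vapply(seq_len(n), function(i) {
      draw_utr5(utr5_len[i], target[i], gc,
                params$pes_window, params$pes_min_run)
    }, character(1))

    pool <- sense_codons()
    pool_prob <- vapply(strsplit(pool, ""), function(cc)
      prod(base_probs(gc)[cc]), numeric(1))
    n_sense <- codons - 2L
    all_sense <- sample(pool, sum(n_sense), replace = TRUE,
                        prob = pool_prob)
    stops <- sample(c("TAA", "TAG", "TGA"), n, replace = TRUE)
    idx <- rep.int(seq_len(n), n_sense)
    body <- vapply(split(all_sense, factor(idx, levels = seq_len(n))),
                   paste, character(1), collapse = "")
    cds <- paste0("ATG", body, stops)

    utr3 <- vapply(utr3_len, function(l)
      paste(random_bases(l, gc), collapse = ""), character(1))

    ids <- sprintf("TX%04d", seq_len(n))
    models <- transcript_models(
      transcript_id = ids,
      gene_id = sprintf("GENE%04d", seq_len(n)),
      sequence = paste0(utr5, cds, utr3),
      cds_start = utr5_len,
      cds_end = utr5_len + codons * 3L
    )
    truth <- data.table(
      transcript_id = ids,
      gene_id = models$gene_id,
      pes_flag = pes,
      motif_class = target
    )
    list(models = models, truth = truth)
  })
}
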