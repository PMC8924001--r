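#' Classify the 5' end of a transcript as TOP, PES or neither
#'
#' Scores pyrimidine-enriched sequences (PES) near the transcription start
#' site. A transcript carries a PES when a run of at least `min_run`
#' consecutive pyrimidines (C/U) begins within the first `window` nucleotides
#' of the 5' UTR. It is additionally a 5' terminal oligopyrimidine tract
#' (TOP) when the first transcribed nucleotide is a C and the qualifying run
#' starts at position 1. TOP is therefore always a subset of PES.
#'
#' @param utr5_sequence Character vector of 5' UTR sequences (may be empty
#'   strings). `U` and `T` are equivalent; IUPAC ambiguity codes are allowed
#'   and count as non-pyrimidine.
#' @param window Scan window from the TSS, nt (default 10).
#' @param min_run Minimum pyrimidine run length (default 5).
#' @return A character vector with values `"TOP"`, `"PES_non_TOP"` or
#'   `"none"`.
#' @examples
#' classify_5prime_motif(c("CCUUUCAGGAAG", "GGCCUUUUUAGG", "GAGAGAGAGAGA"))
#' @export
classify_5prime_motif <- function(utr5_sequence, window = 10L,
                                  min_run = 5L) {
  stopifnot(window >= 1L, min_run >= 1L)
  s <- gsub("U", "T", toupper(utr5_sequence), fixed = TRUE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", s)
  if (any(bad))
    stop("non-IUPAC characters in UTR sequence(s): ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  out <- rep("none", length(s))
  nonempty <- which(nzchar(s))
  if (length(nonempty)) {
    runs <- gregexpr("[CT]+", s[nonempty])
    hit <- vapply(seq_along(nonempty), function(i) {
      m <- runs[[i]]
      if (m[1] == -1L) return("none")
      len <- attr(m, "match.length")
      qual <- m <= window & len >= min_run
      if (!any(qual)) return("none")
      if (any(m[qual] == 1L) && substr(s[nonempty[i]], 1L, 1L) == "C")
        "TOP" else "PES_non_TOP"
    }, character(1))
    out[nonempty] <- hit
  }
  out
}

#' 5' UTR feature table
#'
#' Computes, per transcript, the 5' UTR length, its GC content and the
#' motif class from [classify_5prime_motif()]. GC content of a zero-length
#' UTR is `NA`.
#'
#' @param models A `transcript_models` table.
#' @inheritParams classify_5prime_motif
#' @return A `data.table` with columns `transcript_id`, `utr5_length`,
#'   `gc_content`, `motif_class`, `pes_flag`.
#' @export
utr_features <- function(models, window = 10L, min_run = 5L) {
  utr5 <- region_sequence(models, "utr5")
  n_gc <- nchar(gsub("[^GCgcSs]", "", utr5))
  len <- nchar(utr5)
  cls <- classify_5prime_motif(utr5, window = window, min_run = min_run)
  data.table(
    transcript_id = models$transcript_id,
    utr5_length = len,
    gc_content = ifelse(len > 0L, n_gc / len, NA_real_),
    motif_class = cls,
    pes_flag = cls != "none"
  )
}

#' Hypergeometric enrichment of a flagged feature in a gene set
#'
#' Upper-tail hypergeometric test for over-representation of a binary
#' feature (for example a 5' PES) among a sample of transcripts (for example
#' the up-translated set) drawn from a population (the testable
#' transcripts). The p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param population_flags Named logical vector: one entry per population
#'   transcript, `TRUE` when the feature is present.
#' @param sample_ids Character vector of transcript ids forming the sample;
#'   must be a subset of `names(population_flags)`.
#' @return A list of class `enrichment_result` with fields `N`, `K`, `n`,
#'   `k`, `p_hyper` and `fold_enrichment` = `(k/n)/(K/N)`.
#' @export
hypergeometric_enrichment <- function(population_flags, sample_ids) {
  if (is.null(names(population_flags)))
    stop("`population_flags` must be named by transcript id", call. = FALSE)
  N <- length(population_flags)
  n <- length(sample_ids)
  if (N == 0L || n == 0L)
    stop("population and sample must be non-empty", call. = FALSE)
  missing <- setdiff(sample_ids, names(population_flags))
  if (length(missing))
    stop("sample ids outside population: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  K <- sum(population_flags)
  k <- sum(population_flags[sample_ids])
  res <- list(
    N = N, K = K, n = n, k = k,
    p_hyper = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    fold_enrichment = if (K > 0L) (k / n) / (K / N) else NA_real_
  )
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric enrichment: k = %d / n = %d in sample vs K = %d / N = %d\n",
    x$k, x$n, x$K, x$N))
  cat(sprintf("  fold enrichment = %.3f, upper-tail p = %.3g\n",
              x$fold_enrichment, x$p_hyper))
  invisible(x)
}

#' Share of PES-bearing transcripts in a sample
#'
#' @param features A `utr_features` table (or any table with `motif_class`
#'   and `pes_flag` columns) restricted to the sample of interest.
#' @return A list with `fraction` (share of `pes_flag`), `n`, and counts
#'   `n_pes`, `n_top`, `n_pes_non_top`.
#' @export
pes_fraction <- function(features) {
  if (!nrow(features)) stop("empty sample", call. = FALSE)
  list(
    fraction = mean(features$pes_flag),
    n = nrow(features),
    n_pes = sum(features$pes_flag),
    n_top = sum(features$motif_class == "TOP"),
    n_pes_non_top = sum(features$motif_class == "PES_non_TOP")
  )
}
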