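#' Estimate P-site offsets from start-codon metagene signal
#'
#' For each read length L the offset is the modal distance between a read's
#' 5' end and the annotated start codon, over reads whose 5' end falls in
#' the window `[cds_start - window, cds_start)`. Initiating ribosomes pile
#' up with their P-site on the start codon, so this mode is the
#' length-specific 5'-end-to-P-site distance. Ties are broken toward the
#' smaller offset; lengths with fewer than `min_reads` window reads inherit
#' the modal offset of the pooled (all-length) signal.
#'
#' @param profile A `ribo_profile` table (footprint 5'-end counts).
#' @param models A `transcript_models` table.
#' @param window Metagene window upstream of the start codon, nt.
#' @param min_reads Minimum window reads for a length-specific mode.
#' @return A `data.table` of class `psite_offsets` with columns
#'   `read_length`, `offset`, `n_start_reads`, `inherited`.
#' @export
estimate_psite_offsets <- function(profile, models, window = 30L,
                                   min_reads = 50L) {
  stopifnot(window >= 1L, min_reads >= 1L)
  ann <- models[, .(transcript_id, cds_start)]
  dt <- merge(as.data.table(profile), ann, by = "transcript_id")
  dt[, candidate := cds_start - position]
  dt <- dt[candidate >= 1L & candidate <= window &
             candidate <= read_length - 1L]
  if (!nrow(dt))
    stop("no footprint 5' ends in any start-codon window; check the ",
         "annotation and profiles (a synthetic run with planted offsets ",
         "can isolate the problem)", call. = FALSE)
  global_mode <- as.integer(weighted_mode_min(dt$candidate, dt$count))
  per_len <- dt[, .(n_start_reads = sum(count),
                    offset = as.integer(
                      weighted_mode_min(candidate, count))),
                by = read_length]
  per_len[, inherited := n_start_reads < min_reads]
  per_len[inherited == TRUE, offset := global_mode]
  ## lengths present in the library but absent from every start window
  seen <- setdiff(unique(profile$read_length), per_len$read_length)
  if (length(seen))
    per_len <- rbind(per_len,
                     data.table(read_length = seen, n_start_reads = 0L,
                                offset = global_mode, inherited = TRUE))
  setorder(per_len, read_length)
  setcolorder(per_len, c("read_length", "offset", "n_start_reads",
                         "inherited"))
  setattr(per_len, "class", c("psite_offsets", class(per_len)))
  per_len[]
}

## Attach P-site coordinates to a profile; reads with lengths missing from
## the offset table are dropped.
psite_positions <- function(profile, offsets, models) {
  dt <- merge(as.data.table(profile),
              as.data.table(offsets)[, .(read_length, offset)],
              by = "read_length")
  dt <- merge(dt, models[, .(transcript_id, length, cds_start, cds_end)],
              by = "transcript_id")
  dt[, psite := position + offset]
  dt[psite >= 0L & psite < length]
}

#' Trinucleotide periodicity and region occupancy report
#'
#' Converts 5' ends to P-sites using the offset table, then reports (i) the
#' fraction of CDS-internal P-sites in each codon frame and (ii) the
#' percentage of all P-sites falling in the 5' UTR, CDS and 3' UTR.
#'
#' @param profile A `ribo_profile` table.
#' @param offsets A `psite_offsets` table.
#' @param models A `transcript_models` table.
#' @return A list of class `periodicity_report`: `frame_fractions` (named,
#'   frames 0-2, summing to 1), `region_percent` (named, summing to 100),
#'   `n_psites_cds`, `n_psites_total`. All-NA with a warning when no P-site
#'   falls in any CDS.
#' @export
periodicity_report <- function(profile, offsets, models) {
  dt <- psite_positions(profile, offsets, models)
  region <- with(dt, ifelse(psite < cds_start, "utr5",
                            ifelse(psite < cds_end, "cds", "utr3")))
  totals <- tapply(dt$count, factor(region,
                                    c("utr5", "cds", "utr3")), sum)
  totals[is.na(totals)] <- 0
  n_total <- sum(totals)
  cds_dt <- dt[psite >= cds_start & psite < cds_end]
  if (!nrow(cds_dt)) {
    warning("no P-sites within any CDS; periodicity undefined")
    frame_frac <- setNames(rep(NA_real_, 3), paste0("frame", 0:2))
  } else {
    f <- (cds_dt$psite - cds_dt$cds_start) %% 3L
    fc <- tapply(cds_dt$count, factor(f, 0:2), sum)
    fc[is.na(fc)] <- 0
    frame_frac <- setNames(as.numeric(fc / sum(fc)), paste0("frame", 0:2))
  }
  res <- list(
    frame_fractions = frame_frac,
    region_percent = setNames(as.numeric(100 * totals / n_total),
                              c("utr5", "cds", "utr3")),
    n_psites_cds = as.numeric(sum(cds_dt$count)),
    n_psites_total = as.numeric(n_total)
  )
  class(res) <- "periodicity_report"
  res
}

#' @export
print.periodicity_report <- function(x, ...) {
  cat("Periodicity report\n")
  cat(sprintf("  frame fractions: %.3f / %.3f / %.3f (n = %d CDS P-sites)\n",
              x$frame_fractions[1], x$frame_fractions[2],
              x$frame_fractions[3], as.integer(x$n_psites_cds)))
  cat(sprintf("  P-sites by region: 5'UTR %.1f%%, CDS %.1f%%, 3'UTR %.1f%%\n",
              x$region_percent[1], x$region_percent[2],
              x$region_percent[3]))
  invisible(x)
}

#' Region-level read counts and RPKM
#'
#' Counts reads per transcript region (whole transcript = `exon`, `utr5`,
#' `cds`, `utr3`) and converts to reads per kilobase per million mapped
#' reads. In `rpf_psite` mode a read is assigned to the region containing
#' its P-site (offsets required); in `rna_fragment` mode to the region
#' containing its 5' end. Zero-length regions get count 0 and RPKM `NA`.
#'
#' @param profile A `ribo_profile` table.
#' @param models A `transcript_models` table.
#' @param mode `"rpf_psite"` or `"rna_fragment"`.
#' @param offsets A `psite_offsets` table (required for `rpf_psite`).
#' @return A `data.table` of class `region_quant`: `transcript_id`,
#'   `region`, `length`, `count`, `rpkm`; attribute `library_total`.
#' @export
quantify_regions <- function(profile, models,
                             mode = c("rpf_psite", "rna_fragment"),
                             offsets = NULL) {
  mode <- match.arg(mode)
  lib_total <- attr(profile, "library_total")
  if (is.null(lib_total) || lib_total <= 0)
    stop("profile must carry a positive `library_total` attribute",
         call. = FALSE)
  if (mode == "rpf_psite") {
    if (is.null(offsets))
      stop("offsets are required in rpf_psite mode", call. = FALSE)
    dt <- psite_positions(profile, offsets, models)
    dt[, x := psite]
  } else {
    dt <- merge(as.data.table(profile),
                models[, .(transcript_id, length, cds_start, cds_end)],
                by = "transcript_id")
    dt <- dt[position >= 0L & position < length]
    dt[, x := position]
  }
  dt[, region := ifelse(x < cds_start, "utr5",
                        ifelse(x < cds_end, "cds", "utr3"))]
  per_region <- dt[, .(count = sum(count)), by = .(transcript_id, region)]
  exon <- dt[, .(count = sum(count), region = "exon"),
             by = transcript_id]
  counts <- rbind(per_region, exon[, .(transcript_id, region, count)])
  lens <- region_lengths(models)
  out <- merge(lens, counts, by = c("transcript_id", "region"),
               all.x = TRUE)
  out[is.na(count), count := 0L]
  out[, rpkm := ifelse(length > 0L,
                       count / (length / 1e3 * lib_total / 1e6),
                       NA_real_)]
  out[, region := factor(region, c("exon", "utr5", "cds", "utr3"))]
  setorder(out, transcript_id, region)
  out[, region := as.character(region)]
  setattr(out, "library_total", lib_total)
  setattr(out, "mode", mode)
  setattr(out, "class", c("region_quant", class(out)))
  out[]
}

#' Codon occupancy at the E, P or A site
#'
#' Assigns each footprint's decoded codon at the requested ribosomal site
#' (E = P-site codon minus 3 nt, P = the P-site codon, A = plus 3 nt),
#' restricted to positions inside the CDS, and normalizes the per-codon
#' site counts by codon usage across the analyzed CDS regions. With
#' `rescale = TRUE` occupancies are rescaled to mean 1 over observed
#' codons. Codons never present in the analyzed CDSs are `NA`.
#'
#' @param profile A `ribo_profile` table.
#' @param offsets A `psite_offsets` table.
#' @param models A `transcript_models` table.
#' @param site `"E"`, `"P"` or `"A"`.
#' @param rescale Rescale occupancy to mean 1 over observed codons.
#' @return A `data.table` of class `codon_occupancy` with one row per codon
#'   (64): `codon`, `site_count`, `usage`, `occupancy`.
#' @export
codon_occupancy <- function(profile, offsets, models,
                            site = c("P", "E", "A"), rescale = TRUE) {
  site <- match.arg(site)
  shift <- c(E = -3L, P = 0L, A = 3L)[[site]]
  dt <- psite_positions(profile, offsets, models)
  ## codon-aligned site position: codon containing (psite + shift)
  dt[, x := psite + shift]
  dt <- dt[x >= cds_start & x < cds_end]
  ci <- (dt$x - dt$cds_start) %/% 3L
  starts <- dt$cds_start + 3L * ci + 1L
  site_codon <- substring(models$sequence[
    match(dt$transcript_id, models$transcript_id)], starts, starts + 2L)
  site_counts <- tapply(dt$count, site_codon, sum)

  ## codon usage across the CDSs of all profiled transcripts
  used <- models[transcript_id %in% unique(profile$transcript_id)]
  cds_seqs <- region_sequence(used, "cds")
  all_codons <- unlist(lapply(cds_seqs, function(s)
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))))
  usage_counts <- table(all_codons)

  b <- c("A", "C", "G", "T")
  codons64 <- sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
  out <- data.table(codon = codons64)
  out[, site_count := as.numeric(site_counts[codon])]
  out[is.na(site_count), site_count := 0]
  out[, usage := as.numeric(usage_counts[codon])]
  out[is.na(usage), usage := 0]
  out[, occupancy := ifelse(usage > 0,
                            (site_count / sum(site_count)) /
                              (usage / sum(usage)),
                            NA_real_)]
  if (rescale) {
    m <- mean(out$occupancy, na.rm = TRUE)
    if (is.finite(m) && m > 0) out[, occupancy := occupancy / m]
  }
  setattr(out, "site", site)
  setattr(out, "class", c("codon_occupancy", class(out)))
  out[]
}
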