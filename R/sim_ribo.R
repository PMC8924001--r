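#' Parameters for the ribosome-profiling count simulator
#'
#' Describes a two-condition, replicated ribosome-profiling experiment:
#' lognormal transcript abundance, lognormal baseline translation efficiency
#' (TE), and a condition-specific multiplicative TE effect applied to
#' PES-flagged transcripts in the perturbed condition. Footprint P-sites are
#' drawn over CDS codons with a configurable in-frame probability; the
#' recorded 5' end is the P-site minus a read-length-dependent offset.
#' Total-RNA fragments are drawn uniformly over the transcript.
#'
#' @param conditions Two condition labels, reference first.
#' @param abundance_log_mean,abundance_log_sd Lognormal parameters of
#'   transcript abundance.
#' @param base_te_log_mean,base_te_log_sd Lognormal parameters of baseline
#'   TE.
#' @param te_effect_on_pes Multiplicative TE factor (> 0) applied to
#'   PES-flagged transcripts in the perturbed condition.
#' @param read_length_dist Named numeric vector mapping read length (nt) to
#'   probability; must sum to 1.
#' @param offset_by_length Named integer vector mapping read length to
#'   P-site offset (nt from the 5' end); each offset must lie in
#'   `[1, length - 1]`.
#' @param frame0_prob Probability that a P-site falls in frame 0; the
#'   remainder is split evenly between frames 1 and 2.
#' @param depth_rpf,depth_rna Total reads per footprint / total-RNA library.
#' @param replicates Libraries per condition and assay.
#' @param codon_dwell Optional named numeric vector of relative ribosome
#'   dwell times per codon (unnamed codons get 1); `NULL` means uniform.
#' @param start_codon_weight Relative dwell of the initiating ribosome on
#'   the start codon (> 0). Real footprint libraries show a strong
#'   initiation pileup, which is the signal metagene P-site offset
#'   estimation relies on; 1 removes it.
#' @param seed Master seed.
#' @return A list of class `sim_ribo_params`.
#' @export
sim_ribo_params <- function(conditions = c("reference", "perturbed"),
                            abundance_log_mean = 3,
                            abundance_log_sd = 1.2,
                            base_te_log_mean = 0,
                            base_te_log_sd = 0.5,
                            te_effect_on_pes = 4,
                            read_length_dist = c(
                              `26` = 0.03, `27` = 0.08, `28` = 0.25,
                              `29` = 0.35, `30` = 0.18, `31` = 0.08,
                              `32` = 0.03),
                            offset_by_length = c(
                              `26` = 11L, `27` = 11L, `28` = 12L,
                              `29` = 12L, `30` = 13L, `31` = 13L,
                              `32` = 14L),
                            frame0_prob = 0.85,
                            depth_rpf = 2e6,
                            depth_rna = 2e6,
                            replicates = 2L,
                            codon_dwell = NULL,
                            start_codon_weight = 5,
                            seed = 1L) {
  stopifnot(length(conditions) == 2L, !anyDuplicated(conditions))
  if (abs(sum(read_length_dist) - 1) > 1e-8)
    stop("read_length_dist probabilities must sum to 1", call. = FALSE)
  if (is.null(names(read_length_dist)) || is.null(names(offset_by_length)))
    stop("read_length_dist and offset_by_length must be named by length",
         call. = FALSE)
  lens <- as.integer(names(read_length_dist))
  miss <- setdiff(names(read_length_dist), names(offset_by_length))
  if (length(miss))
    stop("offset_by_length missing lengths: ",
         paste(miss, collapse = ", "), call. = FALSE)
  off <- offset_by_length[names(read_length_dist)]
  if (any(off < 1L) || any(off >= lens))
    stop("offsets must lie in [1, read_length - 1]", call. = FALSE)
  check_fraction(frame0_prob, "frame0_prob")
  if (depth_rpf <= 0 || depth_rna <= 0)
    stop("library depths must be > 0", call. = FALSE)
  stopifnot(replicates >= 1L, te_effect_on_pes > 0,
            start_codon_weight > 0)
  structure(
    list(conditions = conditions,
         abundance_log_mean = abundance_log_mean,
         abundance_log_sd = abundance_log_sd,
         base_te_log_mean = base_te_log_mean,
         base_te_log_sd = base_te_log_sd,
         te_effect_on_pes = te_effect_on_pes,
         read_length_dist = read_length_dist,
         offset_by_length = setNames(as.integer(off),
                                     names(read_length_dist)),
         frame0_prob = frame0_prob,
         depth_rpf = depth_rpf,
         depth_rna = depth_rna,
         replicates = as.integer(replicates),
         codon_dwell = codon_dwell,
         start_codon_weight = start_codon_weight,
         seed = as.integer(seed)),
    class = "sim_ribo_params"
  )
}

## Aggregate sampled (transcript, read length, 5' position) triples into a
## sparse count table.
aggregate_reads <- function(tid, len, pos) {
  dt <- data.table(transcript_id = tid, read_length = len, position = pos)
  dt[, .(count = .N), by = .(transcript_id, read_length, position)]
}

#' Simulate footprint and total-RNA count profiles
#'
#' Draws per-library 5'-end count profiles for both assays, conditions and
#' replicates. Expected footprint counts per transcript are proportional to
#' abundance times condition TE; expected RNA counts to abundance times
#' transcript length (fragments sampled from transcript copies). The
#' returned truth table records abundance, per-condition true TE and the
#' true TE log2 fold change.
#'
#' @param models A `transcript_models` table.
#' @param truth Truth table from [simulate_transcriptome()] (needs
#'   `transcript_id` and `pes_flag`).
#' @param params A [sim_ribo_params()] object.
#' @return A list with `counts` (a `ribo_counts` table: `assay`,
#'   `condition`, `replicate`, `transcript_id`, `read_length`, `position`,
#'   `count`, with a `library_totals` attribute) and `truth` (per-transcript
#'   abundance and TE).
#' @export
simulate_ribo_counts <- function(models, truth, params) {
  stopifnot(inherits(params, "sim_ribo_params"), nrow(models) > 0L)
  if (!all(models$transcript_id %in% truth$transcript_id))
    stop("truth table does not cover all transcripts", call. = FALSE)
  with_seed(substream_seed(params$seed, "counts"), {
    n <- nrow(models)
    pes <- truth[match(models$transcript_id, transcript_id), pes_flag]
    abundance <- rlnorm(n, params$abundance_log_mean,
                        params$abundance_log_sd)
    base_te <- rlnorm(n, params$base_te_log_mean, params$base_te_log_sd)
    te <- cbind(base_te, base_te * ifelse(pes, params$te_effect_on_pes, 1))
    colnames(te) <- params$conditions

    ## one cell per CDS codon, reused for every footprint library
    n_cod <- (models$cds_end - models$cds_start) %/% 3L
    cell_tx <- rep.int(seq_len(n), n_cod)
    cell_codon <- sequence(n_cod) - 1L
    cell_w0 <- rep.int(1, length(cell_tx))
    if (!is.null(params$codon_dwell)) {
      starts <- models$cds_start[cell_tx] + 3L * cell_codon + 1L
      cods <- substring(models$sequence[cell_tx], starts, starts + 2L)
      dw <- params$codon_dwell[cods]
      dw[is.na(dw)] <- 1
      cell_w0 <- as.numeric(dw)
    }
    cell_w0[cell_codon == 0L] <- cell_w0[cell_codon == 0L] *
      params$start_codon_weight
    cell_norm <- cell_w0 / rep.int(tapply(cell_w0, cell_tx, sum), n_cod)

    lens <- as.integer(names(params$read_length_dist))
    offs <- params$offset_by_length
    tx_len <- models$length
    cds_start <- models$cds_start

    draw_rpf <- function(cond) {
      w <- cell_norm * (abundance * te[, cond])[cell_tx]
      counts <- as.vector(rmultinom(1L, params$depth_rpf, w))
      ridx <- rep.int(seq_along(counts), counts)
      tx <- cell_tx[ridx]
      codon <- cell_codon[ridx]
      nr <- length(tx)
      frame <- ifelse(runif(nr) < params$frame0_prob, 0L,
                      sample(c(1L, 2L), nr, replace = TRUE))
      L <- sample(lens, nr, replace = TRUE,
                  prob = params$read_length_dist)
      psite <- cds_start[tx] + 3L * codon + frame
      five <- psite - offs[match(L, lens)]
      five <- pmax(0L, pmin(five, tx_len[tx] - L))
      aggregate_reads(models$transcript_id[tx], L, five)
    }

    draw_rna <- function() {
      w <- abundance * tx_len
      counts <- as.vector(rmultinom(1L, params$depth_rna, w))
      tx <- rep.int(seq_len(n), counts)
      nr <- length(tx)
      L <- sample(lens, nr, replace = TRUE,
                  prob = params$read_length_dist)
      pos <- as.integer(floor(runif(nr) * pmax(1L, tx_len[tx] - L + 1L)))
      aggregate_reads(models$transcript_id[tx], L, pos)
    }

    libs <- list(); totals <- list()
    for (cond in params$conditions) {
      for (r in seq_len(params$replicates)) {
        rpf <- draw_rpf(cond)
        rna <- draw_rna()
        libs[[length(libs) + 1L]] <-
          rpf[, `:=`(assay = "rpf", condition = cond, replicate = r)]
        libs[[length(libs) + 1L]] <-
          rna[, `:=`(assay = "rna", condition = cond, replicate = r)]
        totals[[length(totals) + 1L]] <- data.table(
          assay = c("rpf", "rna"), condition = cond, replicate = r,
          library_total = c(params$depth_rpf, params$depth_rna))
      }
    }
    counts <- rbindlist(libs)
    setcolorder(counts, c("assay", "condition", "replicate",
                          "transcript_id", "read_length", "position",
                          "count"))
    setkey(counts, assay, condition, replicate, transcript_id,
           read_length, position)
    setattr(counts, "library_totals", rbindlist(totals))
    setattr(counts, "class", c("ribo_counts", class(counts)))

    te_truth <- data.table(
      transcript_id = models$transcript_id,
      pes_flag = pes,
      abundance = abundance,
      te_reference = te[, 1L],
      te_perturbed = te[, 2L],
      log2fc_te_true = log2(te[, 2L] / te[, 1L])
    )
    setnames(te_truth, c("te_reference", "te_perturbed"),
             paste0("te_", params$conditions))
    list(counts = counts, truth = te_truth)
  })
}

#' Extract one library from a `ribo_counts` table
#'
#' @param counts A `ribo_counts` table.
#' @param assay `"rpf"` or `"rna"`.
#' @param condition Condition label.
#' @param replicate Replicate index.
#' @return A `ribo_profile` `data.table` (`transcript_id`, `read_length`,
#'   `position`, `count`) with a `library_total` attribute.
#' @export
get_profile <- function(counts, assay, condition, replicate) {
  a <- assay; cond <- condition; r <- replicate
  prof <- counts[.(a, cond, r),
                 .(transcript_id, read_length, position, count)]
  prof <- prof[!is.na(transcript_id)]
  totals <- attr(counts, "library_totals")
  tot <- totals[totals$assay == a & totals$condition == cond &
                  totals$replicate == r, ]$library_total
  if (!length(tot)) stop("no such library", call. = FALSE)
  setattr(prof, "library_total", tot)
  setattr(prof, "class", c("ribo_profile", class(prof)))
  prof[]
}

#' Merge ribosome-profiling libraries (e.g. replicates) by summing counts
#'
#' @param ... `ribo_profile` tables.
#' @return A `ribo_profile` with summed counts and summed library totals.
#' @export
merge_profiles <- function(...) {
  profs <- list(...)
  if (length(profs) == 1L && is.list(profs[[1]]) &&
      !is.data.frame(profs[[1]])) profs <- profs[[1]]
  tot <- sum(vapply(profs, function(p) attr(p, "library_total"),
                    numeric(1)))
  merged <- rbindlist(profs)[
    , .(count = sum(count)),
    by = .(transcript_id, read_length, position)]
  setattr(merged, "library_total", tot)
  setattr(merged, "class", c("ribo_profile", class(merged)))
  merged[]
}

#' Write / read count profiles as TSV
#'
#' Columns: `assay`, `condition`, `replicate`, `transcript_id`,
#' `read_length`, `position`, `count`, plus a `library_total` column so the
#' table is self-contained.
#'
#' @param counts A `ribo_counts` table.
#' @param path TSV path.
#' @return `read_ribo_counts` returns a `ribo_counts` table.
#' @export
write_ribo_counts <- function(counts, path) {
  totals <- attr(counts, "library_totals")
  out <- merge(as.data.table(counts), totals,
               by = c("assay", "condition", "replicate"))
  setcolorder(out, c("assay", "condition", "replicate", "transcript_id",
                     "read_length", "position", "count", "library_total"))
  setorder(out, assay, condition, replicate, transcript_id, read_length,
           position)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ribo_counts
#' @export
read_ribo_counts <- function(path) {
  dt <- fread(path, sep = "\t")
  totals <- unique(dt[, .(assay, condition, replicate, library_total)])
  dt[, library_total := NULL]
  setkey(dt, assay, condition, replicate, transcript_id, read_length,
         position)
  setattr(dt, "library_totals", totals)
  setattr(dt, "class", c("ribo_counts", class(dt)))
  dt[]
}
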