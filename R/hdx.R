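#' Maximum exchangeable amides of a peptide
#'
#' Backbone amide count available for deuterium labelling: the two
#' N-terminal residues of a peptic peptide are assumed unable to retain
#' deuterium, and prolines (no backbone amide hydrogen) do not exchange.
#'
#' @param sequence Amino-acid sequence(s), length >= 3.
#' @return Integer vector: `nchar - 2 - (prolines at positions >= 3)`.
#' @examples
#' max_exchangeable("ACDPFG")  # 3
#' @export
max_exchangeable <- function(sequence) {
  s <- toupper(sequence)
  if (any(nchar(s) < 3L))
    stop("peptides must be at least 3 residues long", call. = FALSE)
  tails <- substr(s, 3L, nchar(s))
  n_pro <- nchar(tails) - nchar(gsub("P", "", tails, fixed = TRUE))
  as.integer(nchar(s) - 2L - n_pro)
}

#' Read an HDX state-data table
#'
#' Expects columns `peptide_start`, `peptide_end`, `sequence`, `state`,
#' `exposure_s`, `centroid_mass_da` and optionally `charge`, `confidence`,
#' `retention_time`. Duplicate entries of the same peptide/state/exposure
#' are collapsed: rows whose retention time lies within `rt_window` minutes
#' of the group median are averaged, the rest dropped with a message.
#' Analysis is restricted to the confidence levels in `confidence_keep`.
#'
#' @param path CSV path.
#' @param rt_window Retention-time matching window, minutes.
#' @param confidence_keep Confidence labels retained (default high and
#'   medium).
#' @return A `data.table` of class `hdx_state_data`.
#' @export
read_hdx_csv <- function(path, rt_window = 0.5,
                         confidence_keep = c("high", "medium")) {
  dt <- fread(path)
  req <- c("peptide_start", "peptide_end", "sequence", "state",
           "exposure_s", "centroid_mass_da")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if ("confidence" %in% names(dt)) {
    n0 <- nrow(dt)
    dt <- dt[confidence %in% confidence_keep]
    if (nrow(dt) < n0)
      message(n0 - nrow(dt), " rows outside confidence levels {",
              paste(confidence_keep, collapse = ", "), "} dropped")
  }
  if ("retention_time" %in% names(dt)) {
    dt[, keep := abs(retention_time - median(retention_time)) <=
         rt_window,
       by = .(peptide_start, peptide_end, sequence, state, exposure_s)]
    n_drop <- sum(!dt$keep)
    if (n_drop > 0)
      message(n_drop, " rows outside the ±", rt_window,
              " min retention-time window dropped")
    dt <- dt[keep == TRUE][, keep := NULL]
  }
  dt <- dt[, .(centroid_mass_da = mean(centroid_mass_da)),
           by = .(peptide_start, peptide_end, sequence, state,
                  exposure_s)]
  dt[, peptide_id := sprintf("%d-%d", peptide_start, peptide_end)]
  setattr(dt, "class", c("hdx_state_data", class(dt)))
  dt[]
}

#' Deuterium uptake from centroid masses
#'
#' Uptake is the observed mass difference between the deuterated and
#' non-deuterated peptide: `D(t) = centroid(t) - centroid(0)`, per peptide
#' and state, with no back-exchange correction. Peptides lacking a t = 0
#' centroid in a state are dropped with a message. Negative uptake values
#' are retained and flagged as below-zero artifacts.
#'
#' @param state_table An `hdx_state_data` table (see [read_hdx_csv()]);
#'   any table with `peptide_id`, `peptide_start`, `peptide_end`,
#'   `sequence`, `state`, `exposure_s`, `centroid_mass_da` works.
#' @return A `data.table` of class `uptake_series`: per
#'   peptide/state/timepoint `uptake_da` and `below_zero` flag.
#' @export
compute_uptake <- function(state_table) {
  dt <- as.data.table(state_table)
  if (!"peptide_id" %in% names(dt))
    dt[, peptide_id := sprintf("%d-%d", peptide_start, peptide_end)]
  dt[, centroid_t0 := {
    t0 <- centroid_mass_da[exposure_s == 0]
    if (length(t0)) mean(t0) else NA_real_
  }, by = .(peptide_id, state)]
  dropped <- unique(dt[is.na(centroid_t0),
                       .(peptide_id, state)])
  if (nrow(dropped))
    message(nrow(dropped), " peptide/state series without a t=0 ",
            "centroid dropped: ",
            paste(head(dropped$peptide_id, 5), collapse = ", "))
  dt <- dt[!is.na(centroid_t0)]
  dt[, uptake_da := centroid_mass_da - centroid_t0]
  dt[, below_zero := uptake_da < 0]
  setorder(dt, peptide_id, state, exposure_s)
  setattr(dt, "class", c("uptake_series", class(dt)))
  dt[]
}

#' Normalize uptake to the fraction of maximum
#'
#' Divides uptake by the theoretical maximum given the labelling D2O
#' content and an average deuterium-recovery factor (default 80%), i.e.
#' normalization to 100% D2O content.
#'
#' @param D Uptake values, Da.
#' @param sequence Matching peptide sequence(s) (recycled).
#' @param d2o_fraction D2O content of the labelling buffer.
#' @param recovery Estimated average deuterium recovery in `(0, 1]`.
#' @return Fraction of maximum uptake; `NA` when a peptide has no
#'   exchangeable amide.
#' @export
normalize_uptake <- function(D, sequence, d2o_fraction = 1,
                             recovery = 0.8) {
  check_fraction(d2o_fraction, "d2o_fraction")
  if (recovery <= 0 || recovery > 1)
    stop("`recovery` must be in (0, 1]", call. = FALSE)
  mx <- max_exchangeable(sequence)
  denom <- mx * d2o_fraction * recovery
  ifelse(denom > 0, D / denom, NA_real_)
}

#' Differential deuterium uptake between states
#'
#' Computes, per peptide, the uptake difference ligand minus apo at each
#' shared timepoint and for the maximum uptake across timepoints, and calls
#' significance with a symmetric residual threshold (default +-0.5 Da):
#' `protected` when the difference <= -threshold, `exposed` when
#' >= +threshold, otherwise `ns`. Timepoint grids that differ between
#' states are intersected with a warning.
#'
#' @param uptake An `uptake_series` table containing both states.
#' @param states Length-2 character vector, apo first.
#' @param delta_threshold Significance threshold, Da.
#' @return A list of class `differential_uptake`: `per_time` (peptide x
#'   timepoint differences with calls) and `max` (difference of maximum
#'   uptake per peptide with calls).
#' @export
differential_uptake <- function(uptake, states = c("apo", "ligand"),
                                delta_threshold = 0.5) {
  stopifnot(length(states) == 2L, delta_threshold > 0)
  dt <- as.data.table(uptake)
  missing_states <- setdiff(states, unique(dt$state))
  if (length(missing_states))
    stop("states absent from uptake table: ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  apo <- dt[state == states[1]]
  lig <- dt[state == states[2]]
  t_apo <- sort(unique(apo$exposure_s))
  t_lig <- sort(unique(lig$exposure_s))
  tp <- intersect(t_apo, t_lig)
  if (!identical(t_apo, t_lig))
    warning("timepoint grids differ between states; intersecting to {",
            paste(tp, collapse = ", "), "}")
  per_time <- merge(
    apo[exposure_s %in% tp,
        .(peptide_id, peptide_start, peptide_end, sequence, exposure_s,
          d_apo = uptake_da)],
    lig[exposure_s %in% tp,
        .(peptide_id, exposure_s, d_ligand = uptake_da)],
    by = c("peptide_id", "exposure_s"))
  per_time[, delta_da := d_ligand - d_apo]
  call_delta <- function(x)
    fifelse(x <= -delta_threshold, "protected",
            fifelse(x >= delta_threshold, "exposed", "ns"))
  per_time[, call := call_delta(delta_da)]
  max_dt <- per_time[, .(
    peptide_start = peptide_start[1], peptide_end = peptide_end[1],
    sequence = sequence[1],
    d_apo_max = max(d_apo), d_ligand_max = max(d_ligand),
    delta_da = max(d_ligand) - max(d_apo)), by = peptide_id]
  max_dt[, call := call_delta(delta_da)]
  res <- list(per_time = per_time[], max = max_dt[],
              delta_threshold = delta_threshold, states = states)
  class(res) <- "differential_uptake"
  res
}

#' Residue-level differential uptake map
#'
#' Spreads per-peptide uptake differences onto residues. Each
#' exchange-competent residue of a peptide (positions from `start + 2` to
#' `end`, excluding prolines) receives the unweighted mean of the
#' differences of all peptides covering it; a centered moving average of
#' odd width `smoothing_window` is then applied along each maximal covered
#' run ("heavy smoothing"; width 1 disables it). Residue significance calls
#' use the same +-`delta_threshold` rule on the smoothed values; prolines
#' and uncovered residues are `NA`/`uncovered`.
#'
#' @param diff A `differential_uptake` object.
#' @param protein_length Protein length, residues.
#' @param protein_sequence Optional protein sequence used to mask prolines
#'   at residue level (peptide sequences are always used to mask within
#'   peptides).
#' @param smoothing_window Odd moving-average width, residues.
#' @param delta_threshold Residue-level call threshold, Da (defaults to the
#'   per-peptide threshold in `diff`).
#' @return A list of class `residue_delta_map` with matrices `delta`
#'   (raw means), `smoothed`, character matrix `calls` (rows = residues,
#'   columns = timepoints plus `"max"`), and `coverage` (peptides covering
#'   each residue with competent positions).
#' @export
residue_delta_map <- function(diff, protein_length,
                              protein_sequence = NULL,
                              smoothing_window = 5L,
                              delta_threshold = NULL) {
  stopifnot(inherits(diff, "differential_uptake"),
            smoothing_window >= 1L, smoothing_window %% 2L == 1L)
  thr <- delta_threshold %||% diff$delta_threshold
  peps <- unique(diff$per_time[, .(peptide_id, peptide_start,
                                   peptide_end, sequence)])
  if (any(peps$peptide_start < 1L |
            peps$peptide_end > protein_length))
    stop("peptides outside protein bounds", call. = FALSE)
  tps <- sort(unique(diff$per_time$exposure_s))
  cols <- c(as.character(tps), "max")

  ## competent residues per peptide: start+2 .. end, non-proline
  competent <- lapply(seq_len(nrow(peps)), function(i) {
    p <- peps[i]
    res <- seq.int(p$peptide_start + 2L, p$peptide_end)
    aa <- strsplit(p$sequence, "")[[1]][res - p$peptide_start + 1L]
    res[aa != "P"]
  })
  names(competent) <- peps$peptide_id

  sum_mat <- matrix(0, protein_length, length(cols),
                    dimnames = list(NULL, cols))
  n_mat <- matrix(0L, protein_length, length(cols),
                  dimnames = list(NULL, cols))
  add <- function(pid, col, value) {
    res <- competent[[pid]]
    if (!length(res) || is.na(value)) return()
    sum_mat[res, col] <<- sum_mat[res, col] + value
    n_mat[res, col] <<- n_mat[res, col] + 1L
  }
  pt <- diff$per_time
  for (i in seq_len(nrow(pt)))
    add(pt$peptide_id[i], as.character(pt$exposure_s[i]),
        pt$delta_da[i])
  mx <- diff$max
  for (i in seq_len(nrow(mx)))
    add(mx$peptide_id[i], "max", mx$delta_da[i])

  delta <- ifelse(n_mat > 0L, sum_mat / n_mat, NA_real_)
  if (!is.null(protein_sequence)) {
    pro <- which(strsplit(toupper(protein_sequence), "")[[1]] == "P")
    delta[pro, ] <- NA_real_
  }
  smoothed <- apply(delta, 2L, smooth_runs, window = smoothing_window)
  calls <- ifelse(is.na(smoothed), "uncovered",
                  ifelse(smoothed <= -thr, "protected",
                         ifelse(smoothed >= thr, "exposed", "ns")))
  coverage <- as.integer(apply(n_mat, 1L, max))
  res <- list(delta = delta, smoothed = smoothed, calls = calls,
              coverage = coverage, timepoints = tps,
              smoothing_window = smoothing_window,
              delta_threshold = thr)
  class(res) <- "residue_delta_map"
  res
}

#' Coverage and redundancy statistics of an HDX peptide map
#'
#' @param peptides A table with `peptide_start`, `peptide_end` (1-based
#'   inclusive) and optionally `sequence`; one row per peptide.
#' @param protein_length Protein length, residues.
#' @return A list of class `hdx_qc_stats`: `peptide_count`,
#'   `length_mean`, `length_sd` (residues), `sequence_coverage` (percent
#'   of residues covered by at least one peptide) and `redundancy` (mean
#'   peptides covering each covered residue).
#' @export
hdx_qc <- function(peptides, protein_length) {
  dt <- as.data.table(peptides)
  if (!nrow(dt)) stop("empty peptide list", call. = FALSE)
  lens <- dt$peptide_end - dt$peptide_start + 1L
  cover <- integer(protein_length)
  for (i in seq_len(nrow(dt))) {
    idx <- seq.int(dt$peptide_start[i], dt$peptide_end[i])
    cover[idx] <- cover[idx] + 1L
  }
  covered <- cover > 0L
  res <- list(
    peptide_count = nrow(dt),
    length_mean = mean(lens),
    length_sd = if (nrow(dt) > 1L) sd(lens) else NA_real_,
    sequence_coverage = 100 * mean(covered),
    redundancy = if (any(covered)) mean(cover[covered]) else NA_real_
  )
  class(res) <- "hdx_qc_stats"
  res
}

#' @export
print.hdx_qc_stats <- function(x, ...) {
  cat(sprintf(
    "HDX peptide map: %d peptides, length %.1f +- %.1f aa,\n  %.1f%% sequence coverage, redundancy %.1f\n",
    x$peptide_count, x$length_mean, x$length_sd, x$sequence_coverage,
    x$redundancy))
  invisible(x)
}

#' Write a residue-level difference matrix as CSV
#'
#' Rows are residues, columns the timepoints plus the maximum-uptake
#' difference; values are the smoothed residue differences in Da.
#'
#' @param map A `residue_delta_map`.
#' @param path CSV path.
#' @export
write_residue_delta_csv <- function(map, path) {
  out <- data.table(residue = seq_len(nrow(map$smoothed)))
  for (cn in colnames(map$smoothed))
    out[[paste0("delta_", cn)]] <- map$smoothed[, cn]
  out[["call_max"]] <- map$calls[, "max"]
  out[["coverage"]] <- map$coverage
  fwrite(out, path)
  invisible(path)
}
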