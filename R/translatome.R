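#' Threshold set for differential-translation calling
#'
#' Defaults follow the study design this package implements: an mRNA is
#' called translationally up-regulated when log2(FC TE KO/WT) > 1 with
#' |log2(FC mRNA)| < 1 and a footprint-count FDR < 0.2. Inequalities are
#' strict exactly as stated.
#'
#' @param min_log2fc_te Minimum TE log2 fold change (strict `>`).
#' @param max_abs_log2fc_mrna Transcriptional-change exclusion bound
#'   (strict `<` for calls; `>=` marks `excluded_transcriptional`).
#' @param max_fdr Maximum BH-adjusted footprint-count p-value (strict `<`).
#' @param pseudocount Added to all four pooled counts of a transcript when
#'   any of them is below `min_counts`.
#' @param min_counts Coverage floor triggering the pseudocount.
#' @return A list of class `te_thresholds`.
#' @export
te_thresholds <- function(min_log2fc_te = 1, max_abs_log2fc_mrna = 1,
                          max_fdr = 0.2, pseudocount = 0.5,
                          min_counts = 10) {
  vals <- list(min_log2fc_te = min_log2fc_te,
               max_abs_log2fc_mrna = max_abs_log2fc_mrna,
               max_fdr = max_fdr, pseudocount = pseudocount,
               min_counts = min_counts)
  if (any(vapply(vals, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all thresholds must be positive numbers", call. = FALSE)
  structure(vals, class = "te_thresholds")
}

pool_quants <- function(quants, region_name) {
  stopifnot(length(quants) >= 1L)
  tot <- sum(vapply(quants, function(q) attr(q, "library_total"),
                    numeric(1)))
  pooled <- rbindlist(lapply(quants, as.data.table))[
    region == region_name,
    .(count = sum(count), length = length[1]),
    by = transcript_id]
  list(pooled = pooled, total = tot)
}

rep_rpkm <- function(quants, region_name) {
  rbindlist(lapply(seq_along(quants), function(i) {
    q <- as.data.table(quants[[i]])
    q[region == region_name,
      .(transcript_id, replicate = i, rpkm, count)]
  }))
}

#' Compute translation efficiency per transcript
#'
#' TE is the ratio of footprint density over the CDS to total-mRNA density
#' over the exons: RPKM(CDS, RPF) / RPKM(exons, RNA). Replicates are pooled
#' by summing counts (library totals likewise summed) for the point
#' estimate; per-replicate TEs are retained in the `replicate_te`
#' attribute for diagnostics. When any of a transcript's four pooled counts
#' (RPF/RNA x WT/KO) is below `min_counts`, the pseudocount is added to all
#' four before RPKM so fold changes stay finite. A two-sided Fisher exact
#' test on pooled CDS footprint counts against library totals provides the
#' per-transcript p-value, BH-adjusted across transcripts.
#'
#' @param rpf_wt,rpf_ko Lists of `region_quant` tables (one per replicate)
#'   from [quantify_regions()] in `rpf_psite` mode.
#' @param rna_wt,rna_ko Lists of `region_quant` tables in `rna_fragment`
#'   mode.
#' @param thresholds A [te_thresholds()] object (only `pseudocount` and
#'   `min_counts` are used here).
#' @return A `data.table` of class `te_table`: `transcript_id`, pooled
#'   counts and RPKMs per condition, `te_wt`, `te_ko`, `log2fc_te`,
#'   `log2fc_mrna`, `rpf_p`, `rpf_fdr`, and `translation_class` (set to
#'   `low_coverage` where a transcript is missing in one condition,
#'   otherwise `NA` until [classify_translation()]).
#' @export
compute_te <- function(rpf_wt, rpf_ko, rna_wt, rna_ko,
                       thresholds = te_thresholds()) {
  pw <- pool_quants(rpf_wt, "cds");  pk <- pool_quants(rpf_ko, "cds")
  rw <- pool_quants(rna_wt, "exon"); rk <- pool_quants(rna_ko, "exon")
  m <- Reduce(function(a, b) merge(a, b, by = "transcript_id",
                                   all = TRUE),
              list(
                setnames(copy(pw$pooled), c("count", "length"),
                         c("rpf_cds_count_wt", "cds_length")),
                setnames(copy(pk$pooled), c("count", "length"),
                         c("rpf_cds_count_ko", "cds_length2")),
                setnames(copy(rw$pooled), c("count", "length"),
                         c("rna_exon_count_wt", "exon_length")),
                setnames(copy(rk$pooled), c("count", "length"),
                         c("rna_exon_count_ko", "exon_length2"))))
  m[, cds_length := fifelse(is.na(cds_length), cds_length2, cds_length)]
  m[, exon_length := fifelse(is.na(exon_length), exon_length2,
                             exon_length)]
  m[, c("cds_length2", "exon_length2") := NULL]
  cnt_cols <- c("rpf_cds_count_wt", "rpf_cds_count_ko",
                "rna_exon_count_wt", "rna_exon_count_ko")
  low_cov <- !stats::complete.cases(m[, ..cnt_cols]) |
    is.na(m$cds_length) | is.na(m$exon_length)
  for (cc in cnt_cols) set(m, which(is.na(m[[cc]])), cc, 0)

  ## symmetric pseudocount for under-covered transcripts
  ps <- thresholds$pseudocount
  need <- m[, rpf_cds_count_wt < thresholds$min_counts |
               rpf_cds_count_ko < thresholds$min_counts |
               rna_exon_count_wt < thresholds$min_counts |
               rna_exon_count_ko < thresholds$min_counts]
  adj <- function(x) x + fifelse(need, ps, 0)
  rpkm <- function(count, len_nt, total)
    count / (len_nt / 1e3 * total / 1e6)
  m[, rpf_cds_rpkm_wt := rpkm(adj(rpf_cds_count_wt), cds_length,
                              pw$total)]
  m[, rpf_cds_rpkm_ko := rpkm(adj(rpf_cds_count_ko), cds_length,
                              pk$total)]
  m[, rna_exon_rpkm_wt := rpkm(adj(rna_exon_count_wt), exon_length,
                               rw$total)]
  m[, rna_exon_rpkm_ko := rpkm(adj(rna_exon_count_ko), exon_length,
                               rk$total)]
  m[, te_wt := rpf_cds_rpkm_wt / rna_exon_rpkm_wt]
  m[, te_ko := rpf_cds_rpkm_ko / rna_exon_rpkm_ko]
  m[, log2fc_te := log2(te_ko / te_wt)]
  m[, log2fc_mrna := log2(rna_exon_rpkm_ko / rna_exon_rpkm_wt)]
  m[, rpf_p := rpf_significance(rpf_cds_count_ko, rpf_cds_count_wt,
                                pk$total, pw$total)]
  m[, rpf_fdr := bh_adjust(rpf_p)]
  m[, translation_class := fifelse(low_cov, "low_coverage", NA_character_)]

  rep_te <- merge(
    rep_rpkm(rpf_wt, "cds")[, .(transcript_id, replicate,
                                rpf_rpkm = rpkm)],
    rep_rpkm(rna_wt, "exon")[, .(transcript_id, replicate,
                                 rna_rpkm = rpkm)],
    by = c("transcript_id", "replicate"))
  rep_te[, condition := "wt"]
  rep_te_ko <- merge(
    rep_rpkm(rpf_ko, "cds")[, .(transcript_id, replicate,
                                rpf_rpkm = rpkm)],
    rep_rpkm(rna_ko, "exon")[, .(transcript_id, replicate,
                                 rna_rpkm = rpkm)],
    by = c("transcript_id", "replicate"))
  rep_te_ko[, condition := "ko"]
  rep_all <- rbind(rep_te, rep_te_ko)
  rep_all[, te := rpf_rpkm / rna_rpkm]
  setattr(m, "replicate_te", rep_all[])
  setattr(m, "class", c("te_table", class(m)))
  m[]
}

#' Fisher exact p-value for footprint-count differences
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[count, total - count]` by condition, computed by exact hypergeometric
#' enumeration: conditioning on the margins, the KO count follows
#' `Hypergeometric(total_ko, total_wt, count_ko + count_wt)` and the
#' two-sided p-value sums all outcomes no more probable than the observed
#' one (with the customary `1 + 1e-7` tolerance on the probability
#' comparison). Vectorized over transcripts.
#'
#' @param counts_ko,counts_wt Per-transcript pooled footprint counts.
#' @param total_ko,total_wt Library totals (scalars or vectors).
#' @return Numeric vector of two-sided p-values.
#' @export
rpf_significance <- function(counts_ko, counts_wt, total_ko, total_wt) {
  n <- length(counts_ko)
  stopifnot(length(counts_wt) == n)
  total_ko <- rep_len(total_ko, n); total_wt <- rep_len(total_wt, n)
  if (any(total_ko <= 0) || any(total_wt <= 0))
    stop("library totals must be positive", call. = FALSE)
  if (any(counts_ko > total_ko) || any(counts_wt > total_wt))
    stop("counts exceed library totals", call. = FALSE)
  vapply(seq_len(n), function(i) {
    a <- round(counts_ko[i]); b <- round(counts_wt[i])
    s <- a + b
    if (s == 0) return(1)
    support <- max(0, s - total_wt[i]):min(s, total_ko[i])
    d <- dhyper(support, total_ko[i], total_wt[i], s)
    d_obs <- d[match(a, support)]
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; adjusted values are monotone in rank, at least
#' the raw p, and capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Classify transcripts by differential translation
#'
#' Applies the threshold rules to a [compute_te()] table:
#' `up_translated` iff `log2fc_te > min_log2fc_te` and
#' `|log2fc_mrna| < max_abs_log2fc_mrna` and `rpf_fdr < max_fdr`;
#' `down_translated` symmetrically with `log2fc_te < -min_log2fc_te`;
#' transcripts with `|log2fc_mrna| >= max_abs_log2fc_mrna` are
#' `excluded_transcriptional`; transcripts flagged at TE time remain
#' `low_coverage`; everything else is `unchanged`. The function is a pure
#' function of the thresholds and is idempotent.
#'
#' @param te_table A `te_table` from [compute_te()].
#' @param thresholds A [te_thresholds()] object.
#' @return The table with `translation_class` filled in.
#' @export
classify_translation <- function(te_table, thresholds = te_thresholds()) {
  out <- copy(as.data.table(te_table))
  lc <- !is.na(out$translation_class) &
    out$translation_class == "low_coverage"
  lc <- lc | !is.finite(out$log2fc_te) | !is.finite(out$log2fc_mrna) |
    is.na(out$rpf_fdr)
  excl <- !lc & abs(out$log2fc_mrna) >= thresholds$max_abs_log2fc_mrna
  ok <- !lc & !excl & out$rpf_fdr < thresholds$max_fdr
  up <- ok & out$log2fc_te > thresholds$min_log2fc_te
  down <- ok & out$log2fc_te < -thresholds$min_log2fc_te
  out[, translation_class := "unchanged"]
  out[lc, translation_class := "low_coverage"]
  out[excl, translation_class := "excluded_transcriptional"]
  out[up, translation_class := "up_translated"]
  out[down, translation_class := "down_translated"]
  for (at in c("replicate_te", "library_total"))
    setattr(out, at, attr(te_table, at))
  setattr(out, "thresholds", thresholds)
  setattr(out, "class", c("te_table", class(out)))
  out[]
}

#' Pearson correlation of replicate libraries on log counts
#'
#' @param countsA,countsB Equal-length paired count vectors (n >= 3).
#' @return Pearson r computed on `log2(count + 1)`; `NA` (with a warning)
#'   when either vector has zero variance.
#' @export
replicate_correlation <- function(countsA, countsB) {
  stopifnot(length(countsA) == length(countsB), length(countsA) >= 3L)
  a <- log2(countsA + 1); b <- log2(countsB + 1)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a replicate; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Paired shift test on cumulative TE distributions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-transcript
#' `log2(TE)` values between conditions, with the median log2 shift.
#'
#' @param te_wt,te_ko Paired positive TE vectors.
#' @return A list with `statistic`, `p_value`, `median_shift` (log2 units,
#'   KO minus WT) and `n` (pairs used). All-zero differences give p = 1.
#' @export
cumulative_te_shift <- function(te_wt, te_ko) {
  stopifnot(length(te_wt) == length(te_ko))
  ok <- is.finite(te_wt) & is.finite(te_ko) & te_wt > 0 & te_ko > 0
  d <- log2(te_ko[ok]) - log2(te_wt[ok])
  if (!length(d)) stop("no usable TE pairs", call. = FALSE)
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, median_shift = 0,
                n = length(d)))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided",
                                     exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_shift = median(d), n = length(d))
}

#' Write a TE table with its thresholds manifest
#'
#' @param te_table A classified `te_table`.
#' @param path Output TSV; a JSON manifest echoing the thresholds is
#'   written next to it as `<path>.manifest.json`.
#' @export
write_te_table <- function(te_table, path) {
  fwrite(as.data.table(te_table), path, sep = "\t")
  thr <- attr(te_table, "thresholds")
  if (!is.null(thr))
    jsonlite::write_json(unclass(thr),
                         paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
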