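#' Parameters for the HDX-MS simulator
#'
#' Emulates a bottom-up, centroid-level HDX experiment on a single protein
#' in two states (apo and ligand-bound) under unimodal exchange kinetics:
#' every backbone amide exchanges as a single exponential with its own
#' intrinsic rate, and ligand binding slows the rates inside a planted
#' protection footprint by `protection_factor`. Default timepoints are the
#' 0/30/300/1,000/3,000/9,000 s labelling series.
#'
#' @param protein_length Protein length, residues.
#' @param peptide_mean_length,peptide_sd_length Peptic peptide length
#'   distribution, residues.
#' @param target_redundancy Desired mean peptides per covered residue.
#' @param timepoints Labelling times, seconds; must include 0.
#' @param protected_interval Planted protection footprint,
#'   `c(start, end)` residues (1-based inclusive).
#' @param protection_factor Multiplier in `(0, 1]` on exchange rates inside
#'   the footprint in the ligand state (1 = no protection).
#' @param rate_log_mean,rate_log_sd Lognormal parameters of per-residue
#'   intrinsic exchange rates, 1/s.
#' @param centroid_noise_sd Gaussian noise on each centroid, Da.
#' @param d2o_fraction D2O content of the labelling buffer.
#' @param recovery Average deuterium recovery in `(0, 1]`.
#' @param proline_fraction Fraction of prolines in the random protein
#'   sequence.
#' @param seed Master seed.
#' @return A list of class `sim_hdx_params`.
#' @export
sim_hdx_params <- function(protein_length = 636L,
                           peptide_mean_length = 14.6,
                           peptide_sd_length = 7.9,
                           target_redundancy = 6.9,
                           timepoints = c(0, 30, 300, 1000, 3000, 9000),
                           protected_interval = c(180L, 290L),
                           protection_factor = 0.2,
                           rate_log_mean = log(3e-3),
                           rate_log_sd = 1.5,
                           centroid_noise_sd = 0.05,
                           d2o_fraction = 0.83,
                           recovery = 0.8,
                           proline_fraction = 0.05,
                           seed = 1L) {
  stopifnot(protein_length >= 20L, target_redundancy > 0,
            peptide_mean_length > 3, peptide_sd_length >= 0,
            centroid_noise_sd >= 0)
  if (!0 %in% timepoints)
    stop("timepoints must include 0", call. = FALSE)
  check_range(protected_interval, "protected_interval")
  if (protected_interval[2] > protein_length)
    stop("protected_interval outside protein", call. = FALSE)
  if (protection_factor <= 0 || protection_factor > 1)
    stop("protection_factor must be in (0, 1]", call. = FALSE)
  check_fraction(d2o_fraction, "d2o_fraction")
  if (recovery <= 0 || recovery > 1)
    stop("recovery must be in (0, 1]", call. = FALSE)
  check_fraction(proline_fraction, "proline_fraction")
  structure(
    list(protein_length = as.integer(protein_length),
         peptide_mean_length = peptide_mean_length,
         peptide_sd_length = peptide_sd_length,
         target_redundancy = target_redundancy,
         timepoints = sort(unique(timepoints)),
         protected_interval = as.integer(protected_interval),
         protection_factor = protection_factor,
         rate_log_mean = rate_log_mean,
         rate_log_sd = rate_log_sd,
         centroid_noise_sd = centroid_noise_sd,
         d2o_fraction = d2o_fraction,
         recovery = recovery,
         proline_fraction = proline_fraction,
         seed = as.integer(seed)),
    class = "sim_hdx_params"
  )
}

## average residue masses (Da) for centroid construction
aa_masses <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, E = 129.12,
  Q = 128.13, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13)

#' Simulate an HDX-MS state-data table with a planted protection footprint
#'
#' Generates a random protein, a peptic peptide map sized to hit the target
#' redundancy, per-residue lognormal exchange rates, and centroid masses
#' for apo and ligand states at every timepoint. Peptide deuterium content
#' at time t is the sum over its exchange-competent residues (positions
#' from start + 2, non-proline) of
#' `d2o_fraction * recovery * (1 - exp(-k_i * t))`, with `k_i` multiplied
#' by `protection_factor` inside the protected interval in the ligand
#' state; Gaussian noise is added to each centroid independently.
#'
#' @param params A [sim_hdx_params()] object.
#' @return A list with `state_data` (an `hdx_state_data` table),
#'   `peptides` (peptide map), `protein_sequence`, and `truth`
#'   (per-residue rates and protection mask).
#' @export
simulate_hdx <- function(params) {
  stopifnot(inherits(params, "sim_hdx_params"))
  with_seed(substream_seed(params$seed, "hdx"), {
    L <- params$protein_length
    aas <- names(aa_masses)
    prob <- rep((1 - params$proline_fraction) / 19, 20)
    prob[aas == "P"] <- params$proline_fraction
    protein <- sample(aas, L, replace = TRUE, prob = prob)
    protein_seq <- paste(protein, collapse = "")

    rate <- rlnorm(L, params$rate_log_mean, params$rate_log_sd)
    protected <- seq_len(L) >= params$protected_interval[1] &
      seq_len(L) <= params$protected_interval[2]
    rate_ligand <- rate * ifelse(protected, params$protection_factor, 1)

    n_pep <- max(3L, round(params$target_redundancy * L /
                             params$peptide_mean_length))
    plen <- pmin(pmax(round(rnorm(n_pep, params$peptide_mean_length,
                                  params$peptide_sd_length)), 5L), 40L)
    pstart <- vapply(plen, function(l) sample.int(L - l + 1L, 1L),
                     integer(1))
    peptides <- data.table(
      peptide_start = pstart,
      peptide_end = pstart + plen - 1L
    )
    peptides[, sequence := substring(protein_seq, peptide_start,
                                     peptide_end)]
    peptides[, charge := sample(2:4, .N, replace = TRUE)]
    peptides[, peptide_id := sprintf("%d-%d", peptide_start, peptide_end)]
    peptides <- unique(peptides, by = "peptide_id")
    peptides[, confidence := sample(c("high", "medium"), .N,
                                    replace = TRUE, prob = c(0.35, 0.65))]
    peptides[, retention_time := round(runif(.N, 2, 12), 2)]

    base_mass <- vapply(peptides$sequence, function(s)
      sum(aa_masses[strsplit(s, "")[[1]]]) + 18.02, numeric(1))

    gain <- params$d2o_fraction * params$recovery
    uptake_at <- function(i, t, rates) {
      res <- seq.int(peptides$peptide_start[i] + 2L,
                     peptides$peptide_end[i])
      res <- res[protein[res] != "P"]
      if (!length(res) || t == 0) return(0)
      sum(gain * (1 - exp(-rates[res] * t)))
    }

    grid <- CJ(i = seq_len(nrow(peptides)), state = c("apo", "ligand"),
               exposure_s = params$timepoints)
    grid[, uptake := vapply(seq_len(.N), function(r) {
      uptake_at(i[r], exposure_s[r],
                if (state[r] == "apo") rate else rate_ligand)
    }, numeric(1))]
    grid[, centroid_mass_da := base_mass[i] + uptake +
           rnorm(.N, 0, params$centroid_noise_sd)]
    state_data <- cbind(
      peptides[grid$i, .(peptide_start, peptide_end, sequence, charge,
                         confidence, retention_time, peptide_id)],
      grid[, .(state, exposure_s, centroid_mass_da)])
    setcolorder(state_data,
                c("peptide_id", "peptide_start", "peptide_end",
                  "sequence", "charge", "confidence", "retention_time",
                  "state", "exposure_s", "centroid_mass_da"))
    setattr(state_data, "class", c("hdx_state_data", class(state_data)))

    truth <- data.table(
      residue = seq_len(L),
      amino_acid = protein,
      rate_apo = rate,
      rate_ligand = rate_ligand,
      protected = protected
    )
    list(state_data = state_data[], peptides = peptides[],
         protein_sequence = protein_seq, truth = truth)
  })
}
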