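test_that("transcriptome generator is deterministic and honors the motif truth", {
  par <- sim_transcriptome_params(n_transcripts = 300, pes_fraction = 0.4,
                                  seed = 7)
  a <- simulate_transcriptome(par)
  b <- simulate_transcriptome(par)
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_transcript_fasta(a$models, f1)
  write_transcript_fasta(b$models, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## truth table must match the classifier output exactly
  feats <- utr_features(a$models)
  expect_identical(feats$motif_class, a$truth$motif_class)
  expect_identical(feats$pes_flag, a$truth$pes_flag)

  ## planted share consistent with a Binomial(n, 0.4) draw
  n <- nrow(a$truth)
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(a$truth$pes_flag) - 0.4), 4 * se)
})

test_that("structural invariants of generated transcripts hold", {
  sim <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 50, seed = 3))
  m <- sim$models
  expect_true(all((m$cds_end - m$cds_start) %% 3 == 0))
  expect_true(all(m$cds_start > 0 & m$cds_end < m$length))
  cds <- substr(m$sequence, m$cds_start + 1, m$cds_end)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                    c("TAA", "TAG", "TGA")))
})

test_that("pes_fraction = 0 plants no motifs and degenerate params error", {
  sim <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 60, pes_fraction = 0, seed = 5))
  expect_false(any(sim$truth$pes_flag))
  expect_true(all(utr_features(sim$models)$motif_class == "none"))

  expect_error(sim_transcriptome_params(utr5_length_range = c(30, 20)),
               "interval")
  expect_error(sim_transcriptome_params(pes_fraction = 1.2), "0, 1")
})

test_that("footprint P-sites land in frame 0 when frame0_prob = 1", {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 40, seed = 2))
  par <- sim_ribo_params(frame0_prob = 1, depth_rpf = 2e4,
                         depth_rna = 1e4, replicates = 1, seed = 2)
  sim <- simulate_ribo_counts(tx$models, tx$truth, par)
  rpf <- sim$counts[assay == "rpf"]
  off <- par$offset_by_length[
    match(rpf$read_length, as.integer(names(par$read_length_dist)))]
  psite <- rpf$position + off
  cds0 <- tx$models$cds_start[
    match(rpf$transcript_id, tx$models$transcript_id)]
  expect_true(all((psite - cds0) %% 3 == 0))
})

test_that("TE truth table reflects the planted PES effect exactly", {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 200, pes_fraction = 0.3, seed = 9))
  sim <- simulate_ribo_counts(tx$models, tx$truth, sim_ribo_params(
    te_effect_on_pes = 4, depth_rpf = 1e4, depth_rna = 1e4,
    replicates = 1, seed = 9))
  tr <- sim$truth
  expect_equal(tr[tr$pes_flag]$log2fc_te_true,
               rep(2, sum(tr$pes_flag)))
  expect_equal(tr[!tr$pes_flag]$log2fc_te_true,
               rep(0, sum(!tr$pes_flag)))
  ## expected RPF counts scale with abundance x TE
  expect_error(sim_ribo_params(depth_rpf = 0), "depth")
  expect_error(sim_ribo_params(offset_by_length = c(
    `26` = 26L, `27` = 11L, `28` = 12L, `29` = 12L, `30` = 13L,
    `31` = 13L, `32` = 14L)), "read_length - 1")
})

test_that("HDX simulator obeys its closed-form kinetic limits", {
  ## t = 0: zero uptake before noise
  p0 <- sim_hdx_params(protein_length = 120,
                       protected_interval = c(40, 80),
                       centroid_noise_sd = 0, seed = 4)
  sim <- simulate_hdx(p0)
  up <- suppressMessages(compute_uptake(sim$state_data))
  expect_equal(up[exposure_s == 0]$uptake_da,
               rep(0, sum(up$exposure_s == 0)))

  ## protection_factor = 1: the two states are kinetically identical
  p1 <- sim_hdx_params(protein_length = 120,
                       protected_interval = c(40, 80),
                       protection_factor = 1, centroid_noise_sd = 0,
                       seed = 4)
  s1 <- simulate_hdx(p1)
  apo <- s1$state_data[state == "apo"]
  lig <- s1$state_data[state == "ligand"]
  expect_equal(apo$centroid_mass_da, lig$centroid_mass_da)

  ## t -> Inf, recovery 1, d2o 1: uptake reaches the exchangeable maximum
  p2 <- sim_hdx_params(protein_length = 120,
                       protected_interval = c(40, 80),
                       timepoints = c(0, 1e9), centroid_noise_sd = 0,
                       d2o_fraction = 1, recovery = 1, seed = 4)
  s2 <- simulate_hdx(p2)
  u2 <- suppressMessages(compute_uptake(s2$state_data))
  late <- u2[exposure_s == 1e9 & state == "apo"]
  expect_equal(late$uptake_da, as.numeric(max_exchangeable(late$sequence)),
               tolerance = 1e-6)

  expect_error(sim_hdx_params(timepoints = c(30, 300)), "include 0")
  expect_error(sim_hdx_params(protein_length = 100,
                              protected_interval = c(80, 120)),
               "outside protein")
})

test_that("binding simulator matches the hyperbola at zero noise", {
  par <- sim_binding_params(kd_true = 2, conc_grid = c(0.5, 1, 2, 8, 30, 60),
                            noise_sd = 0, seed = 1)
  b <- simulate_binding(par)
  expect_equal(b[b$concentration_um == 2]$fraction_bound, 0.5)
  expect_equal(b$fraction_bound,
               par$conc_grid / (2 + par$conc_grid))
  big <- simulate_binding(sim_binding_params(
    kd_true = 2, conc_grid = c(1, 2, 4, 1e6), noise_sd = 0, seed = 1))
  expect_gt(big$fraction_bound[4], 0.999)
  expect_error(sim_binding_params(conc_grid = c(3, 1, 2)), "ascending")
})

test_that("substreams keep stages independent under one master seed", {
  s <- vapply(c("transcriptome", "counts", "hdx", "binding"),
              function(st) substream_seed(11, st), integer(1))
  expect_equal(length(unique(s)), 4L)
  expect_true(all(s >= 1 & s < 2^31))
})
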