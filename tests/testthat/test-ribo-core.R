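test_that("P-site offsets are recovered exactly from noiseless simulations", {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 150, seed = 3))
  par <- sim_ribo_params(frame0_prob = 1, depth_rpf = 3e5, depth_rna = 1e4,
                         replicates = 1, seed = 3)
  sim <- simulate_ribo_counts(tx$models, tx$truth, par)
  off <- estimate_psite_offsets(get_profile(sim$counts, "rpf",
                                            "reference", 1), tx$models)
  planted <- par$offset_by_length
  expect_equal(off$offset,
               unname(planted[as.character(off$read_length)]))
  expect_true(all(off$offset >= 1 & off$offset <= off$read_length - 1))
})

test_that("offset estimation handles single reads, ties and empty windows", {
  m <- toy_models()
  ## single read, 5' end 13 nt upstream of T2's start codon, L = 29
  p <- make_profile("T2", 29, 20 - 13, 1)
  off <- estimate_psite_offsets(p, m, min_reads = 1)
  expect_equal(off[off$read_length == 29]$offset, 13L)

  ## bimodal tie {12: 100, 13: 100} resolves to the smaller offset
  p2 <- make_profile(c("T2", "T2"), c(28, 28), c(20 - 12, 20 - 13),
                     c(100, 100))
  off2 <- estimate_psite_offsets(p2, m, min_reads = 1)
  expect_equal(off2$offset, 12L)

  ## sparse lengths inherit the global modal offset
  p3 <- make_profile(c("T2", "T2"), c(28, 31), c(20 - 12, 20 - 9),
                     c(100, 3))
  off3 <- estimate_psite_offsets(p3, m, min_reads = 50)
  expect_equal(off3[off3$read_length == 31]$offset, 12L)
  expect_true(off3[off3$read_length == 31]$inherited)

  ## no reads near any start codon is a hard error
  p4 <- make_profile("T2", 28, 100, 5)
  expect_error(estimate_psite_offsets(p4, m), "start-codon window")
})

test_that("periodicity report reproduces constructed frame structure", {
  m <- toy_models()
  off <- estimate_psite_offsets(make_profile("T2", 28, 20 - 12, 100), m,
                                min_reads = 1)
  ## all P-sites in frame 0 of T2's CDS
  pos_f0 <- 20 + 3 * (0:10) - 12
  r0 <- periodicity_report(make_profile("T2", 28, pos_f0,
                                        rep(5, length(pos_f0))), off, m)
  expect_equal(unname(r0$frame_fractions), c(1, 0, 0))
  ## equal mass on every CDS position gives exactly (1/3, 1/3, 1/3)
  pos_all <- (20:145) - 12
  r1 <- periodicity_report(make_profile("T2", 28, pos_all,
                                        rep(2, length(pos_all))), off, m)
  expect_equal(unname(r1$frame_fractions), rep(1 / 3, 3))
  expect_equal(sum(r1$frame_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(r1$region_percent), 100, tolerance = 1e-6)
})

test_that("periodicity is invariant to transcript order and sharding", {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 60, seed = 8))
  sim <- simulate_ribo_counts(tx$models, tx$truth, sim_ribo_params(
    depth_rpf = 5e4, depth_rna = 1e4, replicates = 1, seed = 8))
  prof <- get_profile(sim$counts, "rpf", "reference", 1)
  off <- estimate_psite_offsets(prof, tx$models)
  ref <- periodicity_report(prof, off, tx$models)

  shuffled <- prof[sample(nrow(prof))]
  setattr(shuffled, "library_total", attr(prof, "library_total"))
  setattr(shuffled, "class", class(prof))
  expect_equal(periodicity_report(shuffled, off, tx$models)$frame_fractions,
               ref$frame_fractions)

  idx <- seq_len(nrow(prof)) %% 2 == 0
  half <- attr(prof, "library_total") / 2
  s1 <- make_profile(prof$transcript_id[idx], prof$read_length[idx],
                     prof$position[idx], prof$count[idx], half)
  s2 <- make_profile(prof$transcript_id[!idx], prof$read_length[!idx],
                     prof$position[!idx], prof$count[!idx], half)
  merged <- merge_profiles(s1, s2)
  expect_equal(periodicity_report(merged, off, tx$models)$frame_fractions,
               ref$frame_fractions)
})

test_that("region RPKM follows its definition and conserves counts", {
  ## 100 reads on a 1,000 nt region in a 1e6-read library -> RPKM 100
  m <- transcript_models("TX", "G", strrep("ACGT", 500), 500L, 1502L)
  off <- data.table::data.table(read_length = 28L, offset = 12L)
  p <- make_profile(rep("TX", 100), 28, seq(500, 1490, 10) - 12,
                    rep(1, 100), library_total = 1e6)
  q <- quantify_regions(p, m, "rpf_psite", off)
  expect_equal(q[q$region == "cds"]$count, 100)
  expect_equal(q[q$region == "cds"]$rpkm, 100 / (1.002), tolerance = 1e-12)

  ## counts conserved across regions; empty profile gives all-zero RPKM
  expect_equal(q[q$region == "exon"]$count,
               sum(q[q$region %in% c("utr5", "cds", "utr3")]$count))
  p0 <- make_profile("TX", 28, 0, 0, library_total = 1e6)
  q0 <- quantify_regions(p0, m, "rna_fragment")
  expect_true(all(q0$count == 0))
  expect_true(all(q0$rpkm[!is.na(q0$rpkm)] == 0))

  ## zero-length region reports NA, never a division by zero
  m3 <- toy_models()
  q3 <- quantify_regions(make_profile("T3", 28, 5, 4, 100), m3,
                         "rna_fragment")
  utr3 <- q3[q3$transcript_id == "T3" & q3$region == "utr3"]
  expect_true(is.na(utr3$rpkm))
  expect_equal(utr3$count, 0)
})

test_that("region quantification matches the per-position oracle", {
  set.seed(41)
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 10, utr5_length_range = c(20, 60),
    cds_codons_range = c(30, 80), utr3_length_range = c(10, 50),
    seed = 41))
  lens <- c(26L, 28L, 30L)
  n <- 400
  prof <- make_profile(
    sample(tx$models$transcript_id, n, replace = TRUE),
    sample(lens, n, replace = TRUE),
    sample(0:320, n, replace = TRUE),
    sample(1:5, n, replace = TRUE),
    library_total = 2e5)
  prof <- prof[, .(count = sum(count)),
               by = .(transcript_id, read_length, position)]
  setattr(prof, "library_total", 2e5)
  off <- data.table::data.table(read_length = lens,
                                offset = c(11L, 12L, 13L))
  for (mode in c("rpf_psite", "rna_fragment")) {
    q <- quantify_regions(prof, tx$models, mode, off)
    oracle <- region_count_oracle(prof, tx$models, mode, off)
    for (key in names(oracle)) {
      parts <- strsplit(key, " ")[[1]]
      got <- q[q$transcript_id == parts[1] & q$region == parts[2]]$count
      expect_equal(got, oracle[[key]],
                   info = paste(mode, key))
    }
  }
})

test_that("codon occupancy is flat under uniform coverage and shifts by site", {
  m <- toy_models()
  off <- data.table::data.table(read_length = 28L, offset = 12L)
  ## T2 CDS: ATG then 40 x GCT then TGA; equal mass on every codon start
  psites <- 20 + 3 * (0:41)
  p <- make_profile(rep("T2", 42), 28, psites - 12, rep(10, 42), 420)
  occ <- codon_occupancy(p, off, m, site = "P")
  seen <- occ[!is.na(occ$occupancy) & occ$site_count > 0]
  expect_equal(seen$occupancy, rep(1, nrow(seen)), tolerance = 1e-12)

  ## A site scores the codon 3' of the P-site codon
  p1 <- make_profile("T2", 28, 20 - 12, 1, 1)  # P-site on ATG
  occA <- codon_occupancy(p1, off, m, site = "A", rescale = FALSE)
  expect_equal(occA[occA$codon == "GCT"]$site_count, 1)
  occE <- codon_occupancy(p1, off, m, site = "E", rescale = FALSE)
  expect_true(all(occE$site_count == 0))  # E site upstream of the CDS
})

test_that("a planted slow codon shows up as elevated occupancy", {
  tx <- simulate_transcriptome(sim_transcriptome_params(
    n_transcripts = 120, seed = 6))
  sim <- simulate_ribo_counts(tx$models, tx$truth, sim_ribo_params(
    codon_dwell = c(AAA = 3), frame0_prob = 1, depth_rpf = 5e5,
    depth_rna = 1e4, replicates = 1, seed = 6))
  prof <- get_profile(sim$counts, "rpf", "reference", 1)
  off <- estimate_psite_offsets(prof, tx$models)
  occ <- codon_occupancy(prof, off, tx$models, site = "P")
  ratio <- occ[occ$codon == "AAA"]$occupancy /
    median(occ$occupancy, na.rm = TRUE)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})
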