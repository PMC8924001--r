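## Build a minimal uptake table for two states over given timepoints.
mini_uptake <- function(d_apo, d_ligand, times = c(0, 100, 1000),
                        start = 5L, end = 15L,
                        sequence = "AGKLMNQRSTV") {
  rows <- data.table::CJ(state = c("apo", "ligand"), exposure_s = times)
  rows$centroid_mass_da <- 1000 +
    ifelse(rows$state == "apo", d_apo[match(rows$exposure_s, times)],
           d_ligand[match(rows$exposure_s, times)])
  rows$peptide_start <- start; rows$peptide_end <- end
  rows$sequence <- sequence
  rows$peptide_id <- sprintf("%d-%d", start, end)
  rows
}

test_that("exchangeable amide counting excludes the N-terminus and prolines", {
  expect_equal(max_exchangeable("ACDEFGHIKL"), 8L)   # len - 2
  expect_equal(max_exchangeable("ACDPFG"), 3L)       # P at position 4
  expect_equal(max_exchangeable("APCDEF"), 4L)       # P inside excluded prefix
  expect_equal(max_exchangeable(c("ACD", "ACDP")), c(1L, 1L))
  expect_error(max_exchangeable("AC"), "3 residues")
})

test_that("uptake is the centroid mass difference from t = 0", {
  tab <- mini_uptake(d_apo = c(0, 3, 4), d_ligand = c(0, 1, 2),
                     times = c(0, 300, 1000))
  tab[tab$state == "apo" & tab$exposure_s == 0,
      "centroid_mass_da"] <- 1542.20
  tab[tab$state == "apo" & tab$exposure_s == 300,
      "centroid_mass_da"] <- 1545.20
  up <- compute_uptake(tab)
  expect_equal(up[up$state == "apo" & up$exposure_s == 300]$uptake_da, 3)
  expect_equal(up[up$exposure_s == 0]$uptake_da, c(0, 0))

  ## below-zero uptake is kept but flagged
  neg <- mini_uptake(d_apo = c(0, -0.4, 1), d_ligand = c(0, 0.5, 1))
  un <- compute_uptake(neg)
  expect_true(un[un$state == "apo" & un$exposure_s == 100]$below_zero)
  expect_equal(un[un$state == "apo" & un$exposure_s == 100]$uptake_da,
               -0.4)

  ## a series without t = 0 is dropped with a message
  no0 <- mini_uptake(c(0, 2, 3), c(0, 1, 2))[exposure_s != 0 |
                                               state != "apo"]
  expect_message(u0 <- compute_uptake(no0), "without a t=0")
  expect_false("apo" %in% u0$state)
})

test_that("normalization to full deuteration applies D2O and recovery", {
  expect_equal(normalize_uptake(3.2, "ACDEFGHIKL", d2o_fraction = 1,
                                recovery = 0.8), 0.5)
  expect_equal(normalize_uptake(0, "ACDEFGHIKL"), 0)
  expect_equal(normalize_uptake(4, "ACDEFGHIKL", 1, 1), 0.5)
  expect_error(normalize_uptake(1, "ACDEFGHIKL", recovery = 0), "0, 1")
  ## monotone in D and bounded by 1/(d2o * recovery) for D <= max
  D <- seq(0, 8, 0.5)
  f <- normalize_uptake(D, "ACDEFGHIKL", 0.9, 0.8)
  expect_true(all(diff(f) > 0))
  expect_true(all(f <= 1 / (0.9 * 0.8) + 1e-12))
})

test_that("differential uptake applies the +-0.5 Da residual criterion", {
  tab <- mini_uptake(d_apo = c(0, 1.0, 2.0), d_ligand = c(0, 0.4, 2.3))
  du <- differential_uptake(compute_uptake(tab))
  pt <- du$per_time
  expect_equal(pt[pt$exposure_s == 100]$delta_da, -0.6)
  expect_equal(pt[pt$exposure_s == 100]$call, "protected")
  expect_equal(pt[pt$exposure_s == 1000]$delta_da, 0.3)
  expect_equal(pt[pt$exposure_s == 1000]$call, "ns")
  expect_equal(du$max$delta_da, 0.3)

  tab2 <- mini_uptake(d_apo = c(0, 1.0, 1.0), d_ligand = c(0, 1.7, 1.7))
  du2 <- differential_uptake(compute_uptake(tab2))
  expect_equal(du2$per_time[exposure_s == 100]$call, "exposed")

  ## mismatched grids intersect with a warning
  t1 <- mini_uptake(c(0, 1, 2), c(0, 1, 2))
  t1 <- t1[!(t1$state == "ligand" & t1$exposure_s == 1000), ]
  expect_warning(du3 <- differential_uptake(compute_uptake(t1)),
                 "intersect")
  expect_equal(sort(unique(du3$per_time$exposure_s)), c(0, 100))
})

test_that("residue map spreads peptide differences onto competent residues", {
  ## single peptide 5..15 with delta -1: residues 7..15 get -1
  tab <- mini_uptake(d_apo = c(0, 2, 2), d_ligand = c(0, 1, 1))
  du <- differential_uptake(compute_uptake(tab))
  m <- residue_delta_map(du, protein_length = 20, smoothing_window = 1)
  expect_equal(unname(m$delta[7:15, "100"]), rep(-1, 9))
  expect_true(all(is.na(m$delta[c(1:6, 16:20), "100"])))
  expect_equal(unname(m$calls[7:15, "max"]), rep("protected", 9))
  expect_equal(unname(m$calls[1, "max"]), "uncovered")

  ## overlapping peptides -1 and 0 average to -0.5 on the shared span
  tab2 <- rbind(tab,
                mini_uptake(d_apo = c(0, 2, 2), d_ligand = c(0, 2, 2),
                            start = 10L, end = 20L,
                            sequence = "AGKLMNQRSTV"))
  du2 <- differential_uptake(compute_uptake(tab2))
  m2 <- residue_delta_map(du2, protein_length = 25, smoothing_window = 1)
  expect_equal(unname(m2$delta[12:15, "100"]), rep(-0.5, 4))
  expect_equal(unname(m2$delta[16:20, "100"]), rep(0, 5))
})

test_that("residue aggregation and smoothing match the brute-force oracle", {
  set.seed(55)
  L <- 150
  n_pep <- 40
  starts <- sample(1:(L - 12), n_pep, replace = TRUE)
  lens <- sample(8:14, n_pep, replace = TRUE)
  aa <- c("A", "G", "K", "L", "P", "S", "T", "V")
  peps <- data.table::data.table(
    peptide_start = starts, peptide_end = pmin(starts + lens, L))
  peps$sequence <- vapply(seq_len(n_pep), function(i)
    paste(sample(aa, peps$peptide_end[i] - peps$peptide_start[i] + 1,
                 replace = TRUE), collapse = ""), character(1))
  peps <- unique(peps, by = c("peptide_start", "peptide_end"))
  deltas <- round(rnorm(nrow(peps), 0, 0.8), 3)

  rows <- data.table::rbindlist(lapply(seq_len(nrow(peps)), function(i)
    mini_uptake(d_apo = c(0, 1, 1), d_ligand = c(0, 1 + deltas[i],
                                                 1 + deltas[i]),
                start = peps$peptide_start[i], end = peps$peptide_end[i],
                sequence = peps$sequence[i])))
  du <- differential_uptake(compute_uptake(rows))
  m <- residue_delta_map(du, L, smoothing_window = 5)

  oracle <- residue_map_oracle(peps, deltas, L)
  expect_equal(unname(m$delta[, "100"]), oracle, tolerance = 1e-10)

  ## smoothing oracle: centered partial-window mean within covered runs
  sm_oracle <- oracle
  runs <- rle(!is.na(oracle))
  ends <- cumsum(runs$lengths); starts_r <- ends - runs$lengths + 1
  for (r in which(runs$values)) {
    for (i in starts_r[r]:ends[r]) {
      lo <- max(starts_r[r], i - 2); hi <- min(ends[r], i + 2)
      sm_oracle[i] <- mean(oracle[lo:hi])
    }
  }
  expect_equal(unname(m$smoothed[, "100"]), sm_oracle, tolerance = 1e-10)
})

test_that("peptide map QC reports coverage and redundancy", {
  one <- data.table::data.table(peptide_start = 1L, peptide_end = 50L)
  qc1 <- hdx_qc(one, 100)
  expect_equal(qc1$sequence_coverage, 50)
  expect_equal(qc1$redundancy, 1)
  qc2 <- hdx_qc(rbind(one, one), 100)
  expect_equal(qc2$redundancy, 2)

  set.seed(9)
  many <- data.table::data.table(
    peptide_start = sample(1:80, 30, replace = TRUE))
  many$peptide_end <- pmin(many$peptide_start + sample(5:20, 30,
                                                       replace = TRUE),
                           100L)
  ref <- hdx_qc(many, 100)
  shuf <- hdx_qc(many[sample(nrow(many))], 100)
  expect_equal(shuf, ref)
  expect_error(hdx_qc(many[0], 100), "empty")
})

test_that("state-data CSV round-trips with retention-time collapsing", {
  sim <- simulate_hdx(sim_hdx_params(protein_length = 120,
                                     protected_interval = c(40, 80),
                                     seed = 13))
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(sim$state_data, path)
  back <- read_hdx_csv(path)
  expect_setequal(unique(back$peptide_id), unique(sim$state_data$peptide_id))
  got <- merge(back,
               sim$state_data[, .(peptide_id, state, exposure_s,
                                  centroid_mass_da)],
               by = c("peptide_id", "state", "exposure_s"))
  expect_equal(got$centroid_mass_da.x, got$centroid_mass_da.y)

  ## an outlier beyond the +-0.5 min window is dropped
  dup <- sim$state_data[1:3]
  dup$retention_time <- dup$retention_time + 5
  data.table::fwrite(rbind(sim$state_data, dup), path)
  expect_message(read_hdx_csv(path), "retention-time window")
})

test_that("simulated peptide maps hit the target redundancy", {
  sim <- simulate_hdx(sim_hdx_params(protein_length = 400,
                                     protected_interval = c(100, 200),
                                     target_redundancy = 7, seed = 19))
  qc <- hdx_qc(sim$peptides, 400)
  expect_lt(abs(qc$redundancy - 7) / 7, 0.1)
})
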