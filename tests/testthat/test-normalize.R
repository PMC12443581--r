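test_that("spike-in anchor is the mean of log2 spike-in intensities", {
  raw <- make_raw(matrix(100, 1, 2), matrix(100, 1, 2),
                  spike5 = c(1024, 1024), spike3 = c(512, 2048))
  expect_equal(spikein_log2_mean(raw, "S1", "cy5"), 10)
  expect_equal(spikein_log2_mean(raw, "S1", "cy3"), 10)  # (9 + 11) / 2
  raw1 <- make_raw(matrix(100, 1, 2), matrix(100, 1, 2),
                   spike5 = 2, spike3 = 2)
  expect_equal(spikein_log2_mean(raw1, "S2", "cy5"), 1)
  expect_error(spikein_log2_mean(raw, "nope", "cy5"), "unknown sample")
})

test_that("channel normalization subtracts the per-sample anchor", {
  raw <- make_raw(matrix(c(1024, 2048), 2, 2), matrix(c(1024, 512), 2, 2),
                  spike5 = c(1024, 1024))
  ip <- normalize_channel(raw, "cy5")
  expect_equal(unname(ip[1, ]), c(0, 0))  # raw at the spike-in level -> 0
  expect_equal(unname(ip[2, ]), c(1, 1))
})

test_that("normalized values are invariant to per-channel rescaling", {
  sim <- simulate_dataset(sim_config(n_transcripts = c(mRNA = 80), seed = 21))
  raw <- sim$raw
  scaled <- raw
  scaled$cy5[, 2] <- scaled$cy5[, 2] * 4        # one sample, one channel
  scaled$cy3[, 5] <- scaled$cy3[, 5] * 0.37     # another, other channel
  a <- normalize_profile(raw)
  b <- normalize_profile(scaled)
  expect_equal(b$ip_norm, a$ip_norm, tolerance = 1e-12)
  expect_equal(b$sup_norm, a$sup_norm, tolerance = 1e-12)
})

test_that("multiple probes per transcript collapse by the median", {
  # spike level 1 makes the anchor 0, so ip_norm = log2(raw)
  raw <- make_raw(matrix(2^c(1, 3, 2, 1, 3), 5, 2),
                  matrix(2^0, 5, 2),
                  spike5 = 1, spike3 = 1,
                  transcript_id = c("TA", "TA", "TA", "TB", "TB"))
  prof <- normalize_profile(raw)
  expect_equal(nrow(prof$transcripts), 2)
  expect_equal(unname(m6a_quantity(prof)["TA", ]), c(2, 2))  # median(1,3,2)
  expect_equal(unname(m6a_quantity(prof)["TB", ]), c(2, 2))  # mean of pair
})

test_that("expression level is the sum of the two normalized channels", {
  raw <- make_raw(matrix(2^1.5, 1, 2), matrix(2^-0.5, 1, 2),
                  spike5 = 1, spike3 = 1)
  prof <- normalize_profile(raw)
  expect_equal(unname(m6a_quantity(prof)[1, ]), c(1.5, 1.5))
  expect_equal(unname(expression_level(prof)[1, ]), c(1, 1))
  # swapping the channels preserves the sum but not the m6A quantity
  swapped <- make_raw(matrix(2^-0.5, 1, 2), matrix(2^1.5, 1, 2),
                      spike5 = 1, spike3 = 1)
  sprof <- normalize_profile(swapped)
  expect_equal(expression_level(sprof), expression_level(prof))
  expect_false(isTRUE(all.equal(m6a_quantity(sprof), m6a_quantity(prof))))
})

test_that("noise-free group differences match the generative closed form", {
  cfg <- sim_config(n_transcripts = c(mRNA = 120), frac_dm_up = 0.2,
                    frac_dm_down = 0.2, frac_de_up = 0.2, frac_de_down = 0.2,
                    noise_sd = 1e-9, frac_absent_flags = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  prof <- normalize_profile(sim$raw)
  tr <- sim$truth
  g1 <- prof$samples$group == "proliferative"
  m6a_diff <- rowMeans(m6a_quantity(prof)[, !g1]) -
    rowMeans(m6a_quantity(prof)[, g1])
  de <- tr$abundance_log2_involuting - tr$abundance_log2_proliferative
  dmeth <- log2(tr$meth_fraction_involuting /
                  tr$meth_fraction_proliferative)
  expect_equal(unname(m6a_diff), de + dmeth, tolerance = 1e-6)
  # expression level shifts by the abundance change in both channels plus
  # the log2 m(1-m) term; it is *not* invariant to the methylated fraction
  expr_diff <- rowMeans(expression_level(prof)[, !g1]) -
    rowMeans(expression_level(prof)[, g1])
  dm1m <- log2((tr$meth_fraction_involuting *
                  (1 - tr$meth_fraction_involuting)) /
               (tr$meth_fraction_proliferative *
                  (1 - tr$meth_fraction_proliferative)))
  expect_equal(unname(expr_diff), 2 * de + dm1m, tolerance = 1e-6)
})

test_that("matched spike-in policy uses only the channel's own controls", {
  probes <- data.frame(
    probe_id = c("PR01", "SPP", "SPN"),
    transcript_id = c("T1", "SPP", "SPN"),
    gene_symbol = c("G1", "SPP", "SPN"),
    rna_class = c("mRNA", NA, NA),
    spikein = c("none", "pos", "neg"), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("S1", "S2"), group = c("g1", "g2"))
  cy5 <- matrix(c(1024, 16, 64), 3, 2)   # pos spike 16, neg spike 64
  cy3 <- matrix(c(1024, 4, 256), 3, 2)
  raw <- raw_array_set(probes, samples, cy5, cy3, matrix("P", 3, 2))
  expect_equal(spikein_log2_mean(raw, "S1", "cy5", policy = "matched"), 4)
  expect_equal(spikein_log2_mean(raw, "S1", "cy5", policy = "all"), 5)
  expect_equal(spikein_log2_mean(raw, "S1", "cy3", policy = "matched"), 8)
  expect_equal(spikein_log2_mean(raw, "S1", "cy3", policy = "all"), 5)
})

test_that("samples without usable spike-ins are dropped with a warning", {
  raw <- make_raw(matrix(100, 2, 4), matrix(100, 2, 4),
                  groups = c("g1", "g1", "g2", "g2"))
  raw$cy5[3:4, 2] <- NA  # kill both spike-ins in sample 2, cy5
  expect_warning(prof <- normalize_profile(raw), "S2")
  expect_equal(prof$samples$sample_id, c("S1", "S3", "S4"))
})
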