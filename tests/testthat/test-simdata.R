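small_cfg <- function(..., seed = 11) {
  sim_config(n_transcripts = c(mRNA = 60, lncRNA = 20, snoRNA = 10),
             seed = seed, ...)
}

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(frac_dm_up = 0.7, frac_dm_down = 0.4),
               "exceeds 1")
  expect_error(small_cfg(frac_dm_up = 0.4, frac_dm_down = 0.3,
                         frac_de_up = 0.3, frac_de_down = 0.2),
               "exceed 1")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(frac_absent_flags = 1.2), "fractions")
  expect_error(sim_config(n_transcripts = c(foo = 10)), "RNA classes")
})

test_that("a null config plants no effects and labels everything null", {
  sim <- simulate_dataset(small_cfg())
  expect_true(all(sim$truth$dm_label == "null"))
  expect_true(all(sim$truth$de_label == "null"))
  expect_equal(sim$truth$meth_fraction_proliferative,
               sim$truth$meth_fraction_involuting)
  expect_equal(sim$truth$abundance_log2_proliferative,
               sim$truth$abundance_log2_involuting)
})

test_that("the same config reproduces the dataset exactly", {
  a <- simulate_dataset(small_cfg(frac_dm_up = 0.1, frac_de_down = 0.1))
  b <- simulate_dataset(small_cfg(frac_dm_up = 0.1, frac_de_down = 0.1))
  expect_identical(a, b)
  c <- simulate_dataset(small_cfg(frac_dm_up = 0.1, frac_de_down = 0.1,
                                  seed = 12))
  expect_false(identical(a$raw$cy5, c$raw$cy5))
})

test_that("truth table respects the generative model", {
  sim <- simulate_dataset(small_cfg(frac_dm_up = 0.2, frac_dm_down = 0.2,
                                    frac_de_up = 0.2, frac_de_down = 0.2))
  tr <- sim$truth
  m <- cbind(tr$meth_fraction_proliferative, tr$meth_fraction_involuting)
  expect_true(all(m > 0 & m < 1))
  up <- tr$dm_label == "up"
  dn <- tr$dm_label == "down"
  expect_true(all(m[up, 2] > m[up, 1]))
  expect_true(all(m[dn, 2] < m[dn, 1]))
  # planted log-odds shift of 1.5 on baselines in (0.05, 0.5) keeps the
  # methylation ratio at or above 1.5 in the changed direction
  expect_true(all(m[up, 2] / m[up, 1] >= 1.5))
  expect_true(all(m[dn, 1] / m[dn, 2] >= 1.5))
  dd <- tr$abundance_log2_involuting - tr$abundance_log2_proliferative
  expect_true(all(abs(dd[tr$de_label == "up"] - 1) < 1e-9))
  expect_true(all(abs(dd[tr$de_label == "down"] + 1) < 1e-9))
  expect_true(all(dd[tr$de_label == "null"] == 0))
  # per-class planting: each class with enough transcripts carries effects
  expect_true(all(table(tr$rna_class[up]) > 0))
})

test_that("coupled configs plant expression changes on the DM transcripts", {
  sim <- simulate_dataset(small_cfg(frac_dm_up = 0.2, frac_dm_down = 0.1,
                                    couple_dm_de = TRUE))
  expect_identical(sim$truth$dm_label, sim$truth$de_label)
})

test_that("channels partition the abundance signal (noise-free limit)", {
  sim <- simulate_dataset(small_cfg(noise_sd = 1e-9))
  raw <- sim$raw
  reg <- raw$probes$spikein == "none"
  tot <- raw$cy5[reg, 1] + raw$cy3[reg, 1]
  # IP + Sup is proportional to 2^abundance, independent of the methylated
  # fraction
  ratio <- log2(tot) - sim$truth$abundance_log2_proliferative
  expect_lt(diff(range(ratio)), 1e-6)
  expect_lt(abs(stats::cor(ratio, sim$truth$meth_fraction_proliferative)),
            0.2)
})

test_that("spike-ins are emitted at fixed nominal levels", {
  sim <- simulate_dataset(small_cfg())
  raw <- sim$raw
  pos <- raw$probes$spikein == "pos"
  neg <- raw$probes$spikein == "neg"
  expect_equal(unique(as.vector(raw$cy5[pos, ])), 0.9 * 2e4)
  expect_equal(unique(as.vector(raw$cy3[pos, ])), 0.1 * 2e4)
  expect_true(all(is.na(raw$cy5[neg, ])))
  expect_true(all(raw$cy3[neg, ] == 2e4))
  expect_true(all(raw$flags[pos | neg, ] == "P"))
})

test_that("absent flags appear at the configured rate", {
  sim <- simulate_dataset(sim_config(
    n_transcripts = c(mRNA = 4000), frac_absent_flags = 0.1, seed = 5))
  reg <- sim$raw$probes$spikein == "none"
  rate <- mean(sim$raw$flags[reg, ] == "A")
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / (4000 * 6)))
})

test_that("noiseless qPCR plates invert the generating formulas exactly", {
  plate <- simulate_qpcr_plate("IGF1", rel_quantity = c(IGF1 = 1),
                               pct_input = c(IGF1 = 50), sigma_ct = 0)
  rel <- ddct_table(plate)
  expect_equal(rel$rel_expr, 1)
  pin <- percent_input_table(plate)
  expect_equal(pin$ct_merip, pin$ct_sup)
  expect_equal(pin$pct_input, 50)

  plate4 <- simulate_qpcr_plate("IGF2", rel_quantity = c(IGF2 = 4),
                                pct_input = c(IGF2 = 20), sigma_ct = 0)
  expect_equal(ddct_table(plate4)$rel_expr, 4)
  expect_equal(percent_input_table(plate4)$pct_input, 20)
})

test_that("recovered ddCt is unbiased under Ct noise", {
  # one single-target plate per replicate keeps recoveries independent
  dd <- vapply(1:300, function(i) {
    plate <- simulate_qpcr_plate("G", rel_quantity = c(G = 2),
                                 sigma_ct = 0.2, seed = 1000 + i)
    ddct_table(plate)$ddct
  }, numeric(1))
  # each ddct averages duplicate wells in 4 reactions: sd = 0.2 * sqrt(4/2)
  se <- 0.2 * sqrt(4 / 2) / sqrt(300)
  expect_lt(abs(mean(dd) - (-1)), 3 * se)
})
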