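test_that("shannon_entropy matches closed-form values and rejects bad input", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  # 75% fixed base / 25% uniform mixture row, against the hand closed form
  p <- c(0.8125, 0.0625, 0.0625, 0.0625)
  expect_equal(shannon_entropy(p), -sum(p * log2(p)))
  expect_equal(round(shannon_entropy(p), 4), 0.9934)
  expect_error(shannon_entropy(c(-0.1, 0.5, 0.3, 0.3)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.5, 0.5, 0)), "sum to 1")
})

test_that("freq_matrix_from_reads counts columns and renormalizes over ambiguous calls", {
  m <- freq_matrix_from_reads(c("AA", "CC", "GG", "TT"), 2)
  expect_equal(unclass(m), matrix(0.25, 2, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
               ignore_attr = TRUE)
  one <- freq_matrix_from_reads("ACGT", 4)
  expect_equal(diag(unclass(one)), rep(1, 4))
  withN <- freq_matrix_from_reads(c("AN", "AC", "AC"), 2)
  expect_equal(unname(unclass(withN)[2, "C"]), 1)  # N excluded, renormalized
  expect_error(freq_matrix_from_reads(c("AC", "ACG"), 2), "length")
})

test_that("analytic matrix is the exact mixture of its components", {
  single <- analytic_freq_matrix(
    data.frame(sequence = "ACGT", proportion = 1), 4)
  expect_true(all(unclass(single) %in% c(0, 1)))
  allN <- analytic_freq_matrix(
    data.frame(sequence = strrep("N", 150), proportion = 1), 150)
  expect_equal(entropy_profile(allN)$mean, 2)
  expect_error(analytic_freq_matrix(
    data.frame(sequence = "AC", proportion = 1), 4), "shorter")
})

test_that("PhiX mixing is the stated linear row operation", {
  m <- analytic_freq_matrix(data.frame(sequence = "AAAA", proportion = 1), 4)
  mixed <- mix_with_phix(m, 0.25)
  expect_equal(unclass(mixed)[1, ], c(A = 0.8125, C = 0.0625, G = 0.0625, T = 0.0625))
  expect_equal(unclass(mix_with_phix(m, 0)), unclass(m))
  expect_equal(entropy_profile(mix_with_phix(m, 1))$mean, 2)
  expect_equal(entropy_profile(mix_with_phix(m, 1))$sd, 0)
  expect_error(mix_with_phix(m, 1.5), "\\[0, 1\\]")
})

test_that("entropy per row is bounded, maximal iff uniform, zero iff constant", {
  set.seed(9)
  for (i in 1:50) {
    p <- stats::rgamma(4, 1); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, 2 + 1e-12)
    if (max(p) == 1) expect_equal(h, 0) else expect_gt(h, 0)
    if (h > 2 - 1e-12) expect_equal(p, rep(0.25, 4))
  }
})

test_that("entropy of a constant row is nondecreasing in the PhiX fraction", {
  m <- analytic_freq_matrix(data.frame(sequence = "G", proportion = 1), 1)
  hs <- vapply(seq(0, 1, by = 0.05),
               function(f) entropy_profile(mix_with_phix(m, f))$mean, 0)
  expect_true(all(diff(hs) >= -1e-12))
  expect_equal(hs[1], 0)
  expect_equal(hs[length(hs)], 2)
})

test_that("control library profile: 6 uniform positions in 150 give 0.08 +/- 0.39", {
  tpl <- synthetic_twister_template()
  prof <- entropy_profile(
    analytic_freq_matrix(read_components(tpl, NULL, synthetic_read_layout()), 150))
  expect_equal(prof$mean, 6 * 2 / 150)              # closed form
  expect_equal(round(prof$sd, 2), 0.39)
  expect_equal(sum(prof$H > 1.999), 6)
})

test_that("simulation converges to the analytic mixture (same components)", {
  tpl <- synthetic_twister_template()
  ins <- synthetic_phased_inserts()
  lay <- synthetic_read_layout()
  exact <- entropy_profile(analytic_freq_matrix(read_components(tpl, ins, lay), 150))
  reads <- simulate_run(tpl, ins, lay, n_reads = 2e5, seed = 123)
  sim <- entropy_profile(freq_matrix_from_reads(reads, 150))
  expect_lt(max(abs(sim$H - exact$H)), 0.015)
  expect_lt(abs(sim$mean - exact$mean), 0.005)
})

test_that("simulated runs are reproducible and respect class fractions", {
  tpl <- small_template(); lay <- small_layout()
  a <- simulate_run(tpl, small_inserts(), lay, n_reads = 500, seed = 21)
  b <- simulate_run(tpl, small_inserts(), lay, n_reads = 500, seed = 21)
  expect_identical(a, b)
  expect_true(all(nchar(a) == lay$read_length))
  # cleaved_fraction = 0: every read carries the uncleaved leader
  dm <- demux_and_trim(a, small_inserts())
  expect_true(all(startsWith(stats::na.omit(dm$trimmed), "GGATT")))
  expect_error(simulate_run(tpl, n_reads = 10), "seed")
})

test_that("per-cycle frequencies of simulated reads agree with a hand tabulation", {
  tpl <- small_template(); lay <- small_layout()
  reads <- simulate_run(tpl, NULL, lay, n_reads = 400, seed = 5)
  m <- freq_matrix_from_reads(reads, lay$read_length)
  for (pos in c(1, 14, 15, 40)) {
    expect_equal(shannon_entropy(unclass(m)[pos, ]), entropy_by_hand(reads, pos))
  }
})

test_that("early-cycle filter window summary reports minima and flags", {
  tpl <- synthetic_twister_template()
  lay <- synthetic_read_layout()
  ins <- synthetic_phased_inserts()
  balanced <- entropy_profile(analytic_freq_matrix(read_components(tpl, ins, lay), 150))
  w9 <- filter_window_summary(balanced, window = 9)
  expect_equal(w9$min, 2)
  expect_equal(w9$mean, 2)

  ctrl <- entropy_profile(analytic_freq_matrix(read_components(tpl, NULL, lay), 150))
  w25 <- filter_window_summary(ctrl, window = 25)
  expect_equal(w25$min, 0)
  expect_true(length(w25$flagged_cycles) > 0)
  expect_length(filter_window_summary(ctrl, 25, threshold = 0)$flagged_cycles, 0)
  expect_error(filter_window_summary(ctrl, window = 151), "exceeds")
})

test_that("genome-mode PhiX mixes with the genome's strand-symmetric composition", {
  g <- strrep("ACGT", 30)
  px <- phix_model(0.5, mode = "genome", genome = g)
  m <- analytic_freq_matrix(data.frame(sequence = "AAAA", proportion = 1), 4)
  mixed <- mix_with_phix(m, px)
  expect_equal(unclass(mixed)[1, ], c(A = 0.625, C = 0.125, G = 0.125, T = 0.125))
  reads <- simulate_run(small_template(), NULL, small_layout(), phix = px,
                        n_reads = 50, seed = 2)
  expect_true(all(nchar(reads) == 40))
})
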