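test_that("degenerate activity settings propagate exactly to the reads", {
  tpl <- small_template(); lay <- small_layout(); ins <- small_inserts()
  genos <- enumerate_genotypes(tpl)
  all_on <- stats::setNames(rep(1, length(genos)), genos)
  run1 <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 1000,
                                          activities = all_on, error_rate = 0,
                                          seed = 2))
  expect_true(all(run1$truth$class == "cleaved"))
  tab1 <- quantify_run(run1$reads, tpl, ins)
  expect_true(all(tab1$w == 1))

  all_off <- stats::setNames(rep(0, length(genos)), genos)
  run0 <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 1000,
                                          activities = all_off, error_rate = 0,
                                          seed = 2))
  expect_identical(sum(run0$truth$class == "cleaved"), 0L)
  tab0 <- quantify_run(run0$reads, tpl, ins)
  expect_true(all(tab0$w == 0))
})

test_that("identical seeds give byte-identical FASTQ output", {
  spec <- synthetic_run_spec(small_template(), small_inserts(), small_layout(),
                             n_reads = 400, error_rate = 0.01, phix = 0.1,
                             seed = 99)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  generate_run(spec, f1)
  generate_run(spec, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("recovered activities sit within 3 binomial SEs of truth at error 0", {
  tpl <- small_template(); lay <- small_layout(); ins <- small_inserts()
  genos <- enumerate_genotypes(tpl)
  set.seed(10)
  acts <- stats::setNames(stats::rbeta(length(genos), 2, 2), genos)
  run <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 8000,
                                         activities = acts, error_rate = 0,
                                         seed = 20))
  tab <- quantify_run(run$reads, tpl, ins)
  # the pipeline adds no error of its own: quantified w equals the w realized
  # in the per-read truth table exactly
  realized <- tapply(run$truth$class == "cleaved", run$truth$genotype, mean)
  expect_equal(as.numeric(realized[tab$genotype]), tab$w)
  # and the realized w sits around the programmed activity with binomial noise
  deep <- tab[tab$n_cleaved + tab$n_uncleaved >= 100, ]
  expect_gt(nrow(deep), 10)
  n <- deep$n_cleaved + deep$n_uncleaved
  truth <- acts[deep$genotype]
  z <- abs(deep$w - truth) / sqrt(truth * (1 - truth) / n)
  expect_true(all(z < 4))
  expect_gte(mean(z <= 3), 0.9)
})

test_that("substitution errors occur at the programmed rate", {
  tpl <- small_template(); lay <- small_layout()
  spec0 <- synthetic_run_spec(tpl, NULL, lay, n_reads = 3000, error_rate = 0,
                              seed = 41)
  spec1 <- synthetic_run_spec(tpl, NULL, lay, n_reads = 3000, error_rate = 0.02,
                              seed = 41)
  clean <- generate_run(spec0)$reads$sequence
  noisy <- generate_run(spec1)$reads$sequence
  # same seed: identical composition before the error stage
  nmis <- sum(vapply(seq_along(clean), function(i) {
    sum(strsplit(clean[i], "")[[1]] != strsplit(noisy[i], "")[[1]])
  }, 0))
  total <- 3000 * lay$read_length
  se <- sqrt(0.02 * 0.98 / total)
  # duplicate positions within a read can collide or revert, so observed
  # mismatches sit at or just below the nominal rate
  expect_lt(nmis / total, 0.02 + 3 * se)
  expect_gt(nmis / total, 0.02 - 3 * se - 0.001)
})

test_that("phix fraction, genotype truth and conservation hold together", {
  tpl <- small_template(); lay <- small_layout(); ins <- small_inserts()
  run <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 4000,
                                         error_rate = 0, phix = 0.25, seed = 55))
  nphix <- sum(run$truth$class == "phix")
  expect_lt(abs(nphix / 4000 - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  tab <- quantify_run(run$reads, tpl, ins)
  expect_identical(attr(tab, "n_assigned") + attr(tab, "n_unassigned") +
                     attr(tab, "n_dropped"), 4000L)
  # phix reads are (almost surely) unassigned at 0 mismatches
  expect_gte(attr(tab, "n_unassigned"), nphix - 5L)
})

test_that("expected read depth and the zero-read probability match simulation", {
  d <- expected_read_depth(4096, 4096)
  expect_equal(d$mean_depth, 1)
  expect_equal(d$zero_read_prob, (1 - 1 / 4096)^4096)
  expect_equal(expected_read_depth(10, 1)$zero_read_prob, 0)

  tpl <- synthetic_twister_template()
  run <- generate_run(synthetic_run_spec(tpl, NULL, synthetic_read_layout(),
                                         n_reads = 4096, error_rate = 0,
                                         seed = 60))
  nz <- sum(!enumerate_genotypes(tpl) %in% run$truth$genotype)
  expected <- d$expected_zero_genotypes
  se <- sqrt(4096 * d$zero_read_prob * (1 - d$zero_read_prob))
  expect_lt(abs(nz - expected), 3 * se)
})

test_that("run spec validates its inputs", {
  tpl <- small_template()
  expect_error(synthetic_run_spec(tpl, n_reads = 10, error_rate = 0.5, seed = 1),
               "error_rate")
  expect_error(synthetic_run_spec(tpl, n_reads = 10, seed = 1,
                                  activities = c(0.5, 0.6)), "named")
  expect_error(synthetic_run_spec(tpl, n_reads = 10), "seed")
  # activities must cover every genotype
  expect_error(generate_run(synthetic_run_spec(tpl, n_reads = 10, seed = 1,
                                               activities = c(AA = 0.5))),
               "missing")
})
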