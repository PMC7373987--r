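test_that("FASTQ write/read round trip is lossless, including gzip and empty files", {
  df <- data.frame(id = c("r1", "r2 extra"), sequence = c("ACGTN", "GGGTT"),
                   quality = c("IIIII", "FFFFF"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fastq")
  write_fastq(df, f)
  expect_identical(read_fastq(f), df)
  # byte-identical after a second round trip
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(read_fastq(f), f2)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))

  gz <- tempfile(fileext = ".fastq.gz")
  write_fastq(df, gz)
  expect_identical(read_fastq(gz), df)

  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_identical(nrow(read_fastq(empty)), 0L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated record
  expect_error(read_fastq(bad), "malformed")
})

test_that("demultiplexing assigns by exact prefix + anchor and trims both", {
  ins <- small_inserts()
  read2 <- paste0(ins$inserts[2], "GGG", "TTTTTTTT")
  dm <- demux_and_trim(read2, ins)
  expect_identical(dm$insert_id, ins$ids[2])
  expect_identical(dm$trimmed, "TTTTTTTT")

  # one substitution inside the insert: rescued only with max_mismatch = 1
  mut <- read2
  substr(mut, 1, 1) <- "T"
  expect_true(is.na(demux_and_trim(mut, ins)$insert_id))
  expect_identical(demux_and_trim(mut, ins, max_mismatch = 1)$insert_id, ins$ids[2])

  # broken anchor is never rescued
  noanchor <- paste0(ins$inserts[2], "GCG", "TTTT")
  expect_true(is.na(demux_and_trim(noanchor, ins, max_mismatch = 2)$insert_id))

  # anchor-only mode
  dm0 <- demux_and_trim(c("GGGACGT", "AGGACGT"), NULL)
  expect_identical(dm0$insert_id, c("none", NA))
  expect_identical(dm0$trimmed, c("ACGT", NA))
})

test_that("mismatch ties break to the longest insert", {
  ins <- phased_insert_set(c("AAAA", "AAATT"), anchor = "GG")
  # one mismatch against both inserts, both anchors intact: longest wins
  amb <- "AAATGGGTTT"
  dm <- demux_and_trim(amb, ins, max_mismatch = 1)
  expect_identical(dm$insert_id, "ins5")
  expect_identical(dm$trimmed, "TTT")
})

test_that("classification separates leader-bearing from cleavage-site reads", {
  tpl <- amplicon_template("toy", "GGAAACCTTTAGCAA", cleavage_site = 5)
  expect_identical(classify_read("GGAAACCTTTAGCAA", tpl), "uncleaved")
  expect_identical(classify_read("CCTTTAGCAA", tpl), "cleaved")
  expect_identical(classify_read("TTTTTTTTTT", tpl), "unassigned")
  expect_identical(classify_read(NA_character_, tpl), "unassigned")
  # randomized positions are wildcards
  tplN <- small_template()
  un <- classify_read("GGATTCGTACGT", tplN)
  cl <- classify_read("CGTACTTGACCT", tplN)
  expect_identical(un, "uncleaved")
  expect_identical(cl, "cleaved")
  # undecidable template: leader and product starts agree over the probe
  undec <- amplicon_template("bad", strrep("G", 12), cleavage_site = 2)
  expect_error(classify_read("GGGGG", undec), "undecidable")
})

test_that("count_genotypes computes w and conserves every input read", {
  tpl <- small_template()
  pr <- data.frame(
    read_id = sprintf("r%d", 1:9),
    insert_id = c(rep("ins2", 8), NA),
    class = c(rep("cleaved", 3), "uncleaved", rep("uncleaved", 4), "unassigned"),
    genotype = c(rep("AC", 4), rep("GT", 4), NA),
    stringsAsFactors = FALSE
  )
  tab <- count_genotypes(pr, tpl)
  expect_equal(tab$w[tab$genotype == "AC"], 0.75)
  expect_equal(tab$w[tab$genotype == "GT"], 0)
  expect_identical(attr(tab, "n_assigned") + attr(tab, "n_unassigned") +
                     attr(tab, "n_dropped"), nrow(pr))

  # ambiguous genotype is dropped and tallied
  pr$genotype[1] <- "NC"
  tab2 <- count_genotypes(pr, tpl)
  expect_identical(unname(attr(tab2, "drop_reasons")["ambiguous_genotype"]), 1L)
  expect_equal(tab2$w[tab2$genotype == "AC"], 2 / 3)
})

test_that("w is invariant to read order", {
  tpl <- small_template(); lay <- small_layout(); ins <- small_inserts()
  run <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 800,
                                         error_rate = 0, seed = 14))
  tab <- quantify_run(run$reads, tpl, ins)
  shuffled <- run$reads[sample(nrow(run$reads)), ]
  tab2 <- quantify_run(shuffled, tpl, ins)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("error-free synthetic reads demultiplex and classify perfectly", {
  tpl <- small_template(); lay <- small_layout(); ins <- small_inserts()
  run <- generate_run(synthetic_run_spec(tpl, ins, lay, n_reads = 5000,
                                         error_rate = 0, seed = 8))
  pr <- process_reads(run$reads, tpl, ins)
  lib <- run$truth$class != "phix"
  expect_identical(pr$insert_id[lib], run$truth$insert_id[lib])
  expect_identical(pr$class[lib], run$truth$class[lib])
  expect_identical(pr$genotype[lib], run$truth$genotype[lib])
})

test_that("optional mean-quality filter drops reads and tallies them", {
  tpl <- small_template(); ins <- small_inserts()
  run <- generate_run(synthetic_run_spec(tpl, ins, small_layout(), n_reads = 50,
                                         error_rate = 0, quality = 20, seed = 4))
  tab <- quantify_run(run$reads, tpl, ins, min_mean_quality = 30)
  expect_identical(nrow(tab), 0L)
  expect_identical(unname(attr(tab, "drop_reasons")["quality_fail"]), 50L)
  tab2 <- quantify_run(run$reads, tpl, ins, min_mean_quality = 10)
  expect_gt(nrow(tab2), 0L)
})

test_that("genotype table TSV round trip with JSON summary", {
  tpl <- small_template(); ins <- small_inserts()
  run <- generate_run(synthetic_run_spec(tpl, ins, small_layout(), n_reads = 300,
                                         error_rate = 0, seed = 31))
  tab <- quantify_run(run$reads, tpl, ins)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_genotype_table(tab, tsv, js)
  back <- read_genotype_table(tsv)
  expect_equal(back$genotype, tab$genotype)
  expect_equal(back$n_cleaved, tab$n_cleaved)
  expect_equal(back$w, tab$w)
  summ <- jsonlite::read_json(js)
  expect_identical(summ$total_reads, 300L)
  expect_identical(summ$n_assigned + summ$n_unassigned + summ$n_dropped, 300L)
})
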