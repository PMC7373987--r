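#' Read or write FASTQ (Phred+33)
#'
#' `read_fastq()` accepts plain or gzipped FASTQ in the standard 4-line
#' record form (`@id`, sequence, `+`, qualities) and returns one row per
#' record, validating record structure, matching sequence/quality lengths
#' and the sequence alphabet; `write_fastq()` writes the same form, gzipped
#' when the path ends in `.gz`. A write/read round trip is lossless.
#'
#' @param path FASTQ file path (`.gz` accepted).
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @return `read_fastq()` returns a data.frame with columns `id`,
#'   `sequence`, `quality` (possibly 0 rows).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) .stopf("cannot open FASTQ '%s'", path)
  lines <- readLines(path)  # file() decompresses gz transparently
  if (length(lines) %% 4L != 0L) {
    .stopf("malformed FASTQ '%s': %d lines, not a multiple of 4 (truncated record near record %d)",
           path, length(lines), length(lines) %/% 4L + 1L)
  }
  if (!length(lines)) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  n <- length(lines) %/% 4L
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) .stopf("malformed FASTQ '%s': record %d", path, bad[1])
  # validate the sequence alphabet
  tryCatch(Biostrings::DNAStringSet(seqs),
           error = function(e) .stopf("malformed FASTQ '%s': %s", path,
                                      conditionMessage(e)))
  data.frame(id = substring(ids, 2L), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    .stopf("sequence and quality lengths differ at record %d",
           which(nchar(reads$sequence) != nchar(reads$quality))[1])
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  n <- nrow(reads)
  if (n) {
    rec <- character(4L * n)
    rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$id)
    rec[seq(2L, by = 4L, length.out = n)] <- reads$sequence
    rec[seq(3L, by = 4L, length.out = n)] <- "+"
    rec[seq(4L, by = 4L, length.out = n)] <- reads$quality
    writeLines(rec, con)
  }
  invisible(reads)
}

#' Assign reads to phased inserts and trim insert + anchor
#'
#' Matches each read's prefix against every insert; a read is assigned to
#' the insert with the fewest prefix mismatches, provided that count is
#' `<= max_mismatch`, ties going to the longest insert (a longer exact-length
#' match is less likely by chance). The anchor must match exactly after the
#' insert. Unassigned reads keep `NA` in both columns. With the default
#' `max_mismatch = 0` and a prefix-free insert set, assignment is exact and
#' unambiguous.
#'
#' @param reads character vector of read sequences (or a data.frame from
#'   [read_fastq()]).
#' @param inserts a [phased_insert_set()], or `NULL` to strip only the anchor.
#' @param max_mismatch substitutions tolerated inside the insert.
#' @return data.frame with columns `insert_id` (`NA` when unassigned) and
#'   `trimmed` (read after insert + anchor).
#' @export
demux_and_trim <- function(reads, inserts = NULL, max_mismatch = 0L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(is.character(reads))
  anchor <- if (is.null(inserts)) "GGG" else inserts$anchor
  n <- length(reads)
  if (is.null(inserts)) {
    ok <- startsWith(reads, anchor)
    return(data.frame(
      insert_id = ifelse(ok, "none", NA_character_),
      trimmed = ifelse(ok, substring(reads, nchar(anchor) + 1L), NA_character_),
      stringsAsFactors = FALSE
    ))
  }
  k <- length(inserts$inserts)
  mm <- matrix(NA_integer_, nrow = n, ncol = k)
  anchor_ok <- matrix(FALSE, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    mm[, j] <- .prefix_mismatches(reads, inserts$inserts[j])
    L <- inserts$lengths[j]
    anchor_ok[, j] <- substr(reads, L + 1L, L + nchar(anchor)) == anchor
  }
  mm[!anchor_ok | is.na(mm)] <- NA_integer_
  mm[mm > max_mismatch] <- NA_integer_
  # fewest mismatches; ties -> longest insert (columns are sorted by length,
  # so take the last minimum)
  best <- rep(NA_integer_, n)
  bestmm <- rep(.Machine$integer.max, n)
  for (j in seq_len(k)) {
    better <- !is.na(mm[, j]) & mm[, j] <= bestmm
    best[better] <- j
    bestmm[better] <- mm[better, j]
  }
  assigned <- !is.na(best)
  trimmed <- rep(NA_character_, n)
  if (any(assigned)) {
    off <- inserts$lengths[best[assigned]] + nchar(anchor)
    trimmed[assigned] <- substring(reads[assigned], off + 1L)
  }
  data.frame(
    insert_id = ifelse(assigned, inserts$ids[best], NA_character_),
    trimmed = trimmed,
    stringsAsFactors = FALSE
  )
}

#' Classify trimmed reads as cleaved or uncleaved
#'
#' An uncleaved read begins at the transcript start (its 5' leader is
#' present); a cleaved read begins at the cleavage site. Each trimmed read's
#' prefix is compared against both candidate template starts over a probe of
#' `probe_length` bases, with randomized (N) template positions acting as
#' wildcards. The class with fewer mismatches wins when within
#' `max_mismatch`; an exact tie (possible only with mismatch tolerance, since
#' a valid template's leader is not a prefix of its product) is conservative:
#' unassigned.
#'
#' @param trimmed character vector of trimmed reads (insert and anchor
#'   removed).
#' @param template an [amplicon_template()].
#' @param max_mismatch substitutions tolerated in the probe.
#' @param probe_length bases compared from each candidate start (default 10,
#'   capped at the cleaved product length).
#' @return Character vector: `"uncleaved"`, `"cleaved"`, or `"unassigned"`
#'   (`NA` input stays unassigned).
#' @export
classify_read <- function(trimmed, template, max_mismatch = 0L,
                          probe_length = 10L) {
  stopifnot(inherits(template, "amplicon_template"))
  cs <- template$cleavage_site
  len <- nchar(template$sequence)
  probe_length <- min(probe_length, len - cs)
  if (probe_length < 1L) .stopf("probe_length must be >= 1")
  pat_u <- substr(template$sequence, 1L, probe_length)
  pat_c <- substr(template$sequence, cs + 1L, cs + probe_length)
  ign_u <- template$degenerate_positions < probe_length
  wild_u <- (template$degenerate_positions[ign_u]) + 1L
  wild_c <- template$degenerate_positions[template$degenerate_positions >= cs &
                                          template$degenerate_positions < cs + probe_length] - cs + 1L
  w_u <- seq_len(probe_length) %in% wild_u
  w_c <- seq_len(probe_length) %in% wild_c
  # configuration check: leader a prefix of the product start => undecidable
  chk <- .prefix_mismatches(pat_c, pat_u, ignore = w_u | w_c)
  if (!is.na(chk) && chk == 0L) {
    .stopf("template '%s' is undecidable: the leader is a prefix of the cleaved product",
           template$name)
  }
  n <- length(trimmed)
  out <- rep("unassigned", n)
  known <- !is.na(trimmed)
  mm_u <- .prefix_mismatches(trimmed[known], pat_u, ignore = w_u)
  mm_c <- .prefix_mismatches(trimmed[known], pat_c, ignore = w_c)
  mm_u[is.na(mm_u) | mm_u > max_mismatch] <- NA_integer_
  mm_c[is.na(mm_c) | mm_c > max_mismatch] <- NA_integer_
  cls <- rep("unassigned", sum(known))
  cls[!is.na(mm_u) & (is.na(mm_c) | mm_u < mm_c)] <- "uncleaved"
  cls[!is.na(mm_c) & (is.na(mm_u) | mm_c < mm_u)] <- "cleaved"
  out[known] <- cls
  out
}

# genotype of each trimmed read: bases at the template's randomized
# positions, coordinates shifted for cleaved reads.
.extract_genotypes <- function(trimmed, class, template) {
  dp <- template$degenerate_positions
  cs <- template$cleavage_site
  if (any(dp < cs)) {
    .stopf("randomized positions upstream of the cleavage site are absent from cleaved reads")
  }
  n <- length(trimmed)
  if (!length(dp)) return(rep("", n))
  geno <- rep(NA_character_, n)
  for (cl in c("uncleaved", "cleaved")) {
    sel <- which(class == cl)
    if (!length(sel)) next
    pos1 <- dp + 1L - if (cl == "cleaved") cs else 0L  # 1-based in trimmed
    cols <- lapply(pos1, function(p) substr(trimmed[sel], p, p))
    geno[sel] <- do.call(paste0, cols)
  }
  geno
}

#' Process reads end to end into per-read assignments
#'
#' Demultiplexes ([demux_and_trim()]), classifies ([classify_read()]) and
#' extracts genotypes for a read collection, with an optional mean-quality
#' filter (off by default; the assay applies no read-level quality filter).
#'
#' @param reads data.frame from [read_fastq()] or a character vector of
#'   sequences.
#' @param template an [amplicon_template()].
#' @param inserts a [phased_insert_set()] or `NULL`.
#' @param max_mismatch substitutions tolerated in the insert prefix.
#' @param max_mismatch_class substitutions tolerated in the classification
#'   probe.
#' @param min_mean_quality drop reads whose mean Phred quality is below this
#'   (requires quality strings; `NULL` disables).
#' @return data.frame with columns `read_id`, `insert_id`, `class`,
#'   `genotype`; one row per input read.
#' @export
process_reads <- function(reads, template, inserts = NULL, max_mismatch = 0L,
                          max_mismatch_class = 0L, min_mean_quality = NULL) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)), sequence = reads,
                        quality = NA_character_, stringsAsFactors = FALSE)
  }
  qual_fail <- rep(FALSE, nrow(reads))
  if (!is.null(min_mean_quality)) {
    if (all(is.na(reads$quality))) .stopf("quality filtering requires quality strings")
    meanq <- vapply(reads$quality,
                    function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE)
    qual_fail <- meanq < min_mean_quality
  }
  dm <- demux_and_trim(reads$sequence, inserts, max_mismatch)
  cls <- classify_read(dm$trimmed, template, max_mismatch_class)
  cls[is.na(dm$insert_id)] <- "unassigned"
  cls[qual_fail] <- "quality_fail"
  geno <- rep(NA_character_, nrow(reads))
  usable <- cls %in% c("uncleaved", "cleaved")
  geno[usable] <- .extract_genotypes(dm$trimmed[usable], cls[usable], template)
  data.frame(read_id = reads$id, insert_id = dm$insert_id, class = cls,
             genotype = geno, stringsAsFactors = FALSE)
}

#' Count cleaved/uncleaved reads per genotype
#'
#' Aggregates processed reads into the per-genotype activity table: cleaved
#' and uncleaved counts and the fraction cleaved
#' `w = n_cleaved / (n_cleaved + n_uncleaved)`. Reads whose genotype contains
#' an ambiguous base are dropped and tallied. Genotypes never observed are
#' absent from the table (compare against [enumerate_genotypes()] to detect
#' them).
#'
#' @param processed data.frame from [process_reads()].
#' @param template an [amplicon_template()].
#' @return data.frame of class `genotype_table` with columns `genotype`,
#'   `n_cleaved`, `n_uncleaved`, `w`, sorted by genotype; attributes
#'   `total_reads`, `n_assigned`, `n_unassigned`, `n_dropped`,
#'   `drop_reasons` (named counts) and `per_insert` (assigned reads per
#'   insert).
#' @export
count_genotypes <- function(processed, template) {
  stopifnot(is.data.frame(processed),
            all(c("insert_id", "class", "genotype") %in% names(processed)))
  k <- length(template$degenerate_positions)
  usable <- processed$class %in% c("uncleaved", "cleaved")
  geno <- processed$genotype[usable]
  cls <- processed$class[usable]
  valid <- !is.na(geno) & nchar(geno) == k &
    !grepl(paste0("[^", paste(.BASES, collapse = ""), "]"), geno)
  drop_reasons <- c(
    unassigned = sum(!usable & processed$class != "quality_fail"),
    quality_fail = sum(processed$class == "quality_fail"),
    ambiguous_genotype = sum(!valid)
  )
  geno <- geno[valid]
  cls <- cls[valid]
  tab <- table(factor(geno), factor(cls, levels = c("cleaved", "uncleaved")))
  df <- data.frame(
    genotype = as.character(rownames(tab)),
    n_cleaved = as.integer(tab[, "cleaved"]),
    n_uncleaved = as.integer(tab[, "uncleaved"]),
    stringsAsFactors = FALSE
  )
  df$w <- ifelse(df$n_cleaved + df$n_uncleaved > 0,
                 df$n_cleaved / (df$n_cleaved + df$n_uncleaved), NA_real_)
  df <- df[order(df$genotype), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "total_reads") <- nrow(processed)
  attr(df, "n_assigned") <- sum(valid)
  attr(df, "n_unassigned") <- drop_reasons[["unassigned"]]
  attr(df, "n_dropped") <- sum(drop_reasons) - drop_reasons[["unassigned"]]
  attr(df, "drop_reasons") <- drop_reasons
  ins <- processed$insert_id[usable][valid]
  attr(df, "per_insert") <- table(ins)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d genotypes, %d/%d reads assigned (%d unassigned, %d dropped)\n",
              nrow(x), attr(x, "n_assigned"), attr(x, "total_reads"),
              attr(x, "n_unassigned"), attr(x, "n_dropped")))
  NextMethod()
}

#' Quantify fraction cleaved per genotype from a FASTQ run
#'
#' Convenience pipeline: FASTQ (or an in-memory read data.frame) ->
#' demultiplex -> classify -> genotype table.
#'
#' @param fastq path to a FASTQ file, or a data.frame from [read_fastq()].
#' @inheritParams process_reads
#' @return A `genotype_table` (see [count_genotypes()]).
#' @export
quantify_run <- function(fastq, template, inserts = NULL, max_mismatch = 0L,
                         max_mismatch_class = 0L, min_mean_quality = NULL) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  pr <- process_reads(reads, template, inserts, max_mismatch,
                      max_mismatch_class, min_mean_quality)
  count_genotypes(pr, template)
}

#' Write a genotype table as TSV with a JSON run summary
#'
#' @param table a `genotype_table`.
#' @param path output TSV (columns genotype, n_cleaved, n_uncleaved, w).
#' @param summary_path optional JSON path for run totals and drop reasons.
#' @return The table, invisibly.
#' @export
write_genotype_table <- function(table, path, summary_path = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(total_reads = attr(table, "total_reads"),
           n_assigned = attr(table, "n_assigned"),
           n_unassigned = attr(table, "n_unassigned"),
           n_dropped = attr(table, "n_dropped"),
           drop_reasons = as.list(attr(table, "drop_reasons")),
           per_insert = as.list(attr(table, "per_insert"))),
      summary_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(table)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(genotype = "character"),
                          stringsAsFactors = FALSE)
  class(df) <- c("genotype_table", "data.frame")
  df
}
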