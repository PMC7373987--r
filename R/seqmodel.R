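#' Amplicon template with degenerate positions and a cleavage site
#'
#' Describes the library construct in transcript orientation (the RNA sense,
#' written as DNA, 5'->3'). Positions holding a non-ACGT IUPAC code are the
#' library's randomized positions; `cleavage_site` is the 0-based offset at
#' which the cleaved ribozyme product begins, so the "leader" lost upon
#' self-cleavage is `substr(sequence, 1, cleavage_site)`. The DNA oligo a
#' vendor would synthesize (template strand, T7 promoter at the 3' end) is the
#' reverse complement of this representation; conversion is I/O, not state.
#'
#' @param name identifier for the construct.
#' @param sequence template sequence over the IUPAC DNA alphabet, transcript
#'   orientation.
#' @param cleavage_site 0-based offset of the first base of the cleaved
#'   product; `0 <= cleavage_site < nchar(sequence)`.
#' @param linker fixed 3' tail (reverse-transcription primer binding site)
#'   that follows the template in every read.
#' @return An object of class `amplicon_template` with fields `name`,
#'   `sequence`, `cleavage_site`, `linker` and `degenerate_positions`
#'   (0-based indices of non-ACGT codes, in sequence order).
#' @examples
#' tpl <- amplicon_template("toy", "GGAAANNNCCTTT", cleavage_site = 5)
#' tpl$degenerate_positions
#' @export
amplicon_template <- function(name, sequence, cleavage_site, linker = "") {
  stopifnot(.is_string(name))
  chars <- .check_dna(sequence, "template sequence")
  if (nzchar(linker)) .check_dna(linker, "linker", alphabet = .BASES)
  if (!is.numeric(cleavage_site) || length(cleavage_site) != 1L ||
      cleavage_site != as.integer(cleavage_site)) {
    .stopf("cleavage_site must be a single integer")
  }
  cleavage_site <- as.integer(cleavage_site)
  if (cleavage_site < 0L || cleavage_site >= length(chars)) {
    .stopf("cleavage_site %d out of range [0, %d)", cleavage_site, length(chars))
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      cleavage_site = cleavage_site,
      linker = linker,
      degenerate_positions = which(!chars %in% .BASES) - 1L
    ),
    class = "amplicon_template"
  )
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat("Amplicon template:", x$name, "\n")
  cat("  length:", nchar(x$sequence), "nt; cleavage site (0-based):",
      x$cleavage_site, "\n")
  cat("  degenerate positions (0-based):",
      if (length(x$degenerate_positions)) paste(x$degenerate_positions, collapse = ", ")
      else "none", "\n")
  cat("  linker:", if (nzchar(x$linker)) x$linker else "<none>", "\n")
  invisible(x)
}

#' Read layout: how a sequencing read is composed, cycle by cycle
#'
#' Cycle 0 is the first sequenced base. An uncleaved read is
#' `[insert] + anchor + template + linker + pad`; a cleaved read replaces the
#' template by its suffix starting at the cleavage site. The anchor is the
#' read-side image of the template-switching oligo's riboguanosines (default
#' `"GGG"`). Reads shorter than `read_length` continue into the linker and
#' then the fixed `pad` (an adapter stub); composing a read whose fixed
#' context still cannot fill `read_length` cycles is an error rather than a
#' silent truncation of the profile.
#'
#' @param read_length cycles per read (default 150).
#' @param anchor fixed bases between insert and transcript-derived sequence.
#' @param pad fixed downstream context appended after the linker.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(read_length = 150L, anchor = "GGG", pad = "") {
  stopifnot(is.numeric(read_length), length(read_length) == 1L, read_length >= 1)
  if (nzchar(anchor)) .check_dna(anchor, "anchor", alphabet = .BASES)
  if (nzchar(pad)) .check_dna(pad, "pad", alphabet = .BASES)
  structure(
    list(read_length = as.integer(read_length), anchor = anchor, pad = pad),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat("Read layout:", x$read_length, "cycles; anchor", x$anchor,
      "; pad", nchar(x$pad), "nt\n")
  invisible(x)
}

# fixed read context that follows an insert, for one read class.
# Returned as IUPAC string (degenerate codes preserved).
.read_context <- function(template, layout, class = c("uncleaved", "cleaved")) {
  class <- match.arg(class)
  body <- if (class == "cleaved") {
    substr(template$sequence, template$cleavage_site + 1L, nchar(template$sequence))
  } else {
    template$sequence
  }
  paste0(layout$anchor, body, template$linker, layout$pad)
}

#' Replace degenerate positions by random concrete bases
#'
#' Draws each degenerate position independently and uniformly from the four
#' bases. Only the fully-random code `N` is supported; the library design this
#' package targets randomizes positions completely, and partially degenerate
#' codes are rejected rather than half-supported.
#'
#' @param template an [amplicon_template()].
#' @param n number of independent concrete sequences to draw.
#' @return Character vector of `n` ACGT-only sequences, equal to
#'   `template$sequence` away from degenerate positions. Uses the current RNG
#'   stream; call `set.seed()` for reproducibility.
#' @examples
#' set.seed(1)
#' expand_degenerate(amplicon_template("t", "ACNGT", 0), n = 3)
#' @export
expand_degenerate <- function(template, n = 1L) {
  stopifnot(inherits(template, "amplicon_template"), n >= 1)
  dp <- template$degenerate_positions
  .reject_non_N(template)
  if (length(dp) == 0L) return(rep(template$sequence, n))
  chunks <- .split_at_positions(template$sequence, dp)
  parts <- vector("list", 2L * length(dp) + 1L)
  for (j in seq_along(dp)) {
    parts[[2L * j - 1L]] <- chunks[j]
    parts[[2L * j]] <- .rand_bases(n)
  }
  parts[[2L * length(dp) + 1L]] <- chunks[length(dp) + 1L]
  do.call(paste0, parts)
}

# split a sequence into fixed chunks around 0-based positions `dp`
.split_at_positions <- function(seq, dp) {
  starts <- c(0L, dp + 1L)         # 0-based chunk starts
  ends <- c(dp, nchar(seq))        # 0-based exclusive chunk ends
  substring(seq, starts + 1L, ends)
}

.reject_non_N <- function(template) {
  dp <- template$degenerate_positions
  if (length(dp) == 0L) return(invisible())
  codes <- substring(template$sequence, dp + 1L, dp + 1L)
  bad <- codes != "N"
  if (any(bad)) {
    .stopf("degenerate code '%s' at 0-based position %d is not supported (only N)",
           codes[bad][1], dp[bad][1])
  }
  invisible()
}

#' Enumerate every genotype of a randomized library
#'
#' A genotype is the string of concrete bases at the template's randomized
#' (`N`) positions, in position order. With k randomized positions there are
#' exactly 4^k genotypes; they are returned in lexicographic order.
#'
#' @param template an [amplicon_template()] whose degenerate codes are all `N`.
#' @return Character vector of length `4^k` (a single empty string when k = 0).
#' @examples
#' length(enumerate_genotypes(amplicon_template("t", "ANNA", 0))) # 16
#' @export
enumerate_genotypes <- function(template) {
  stopifnot(inherits(template, "amplicon_template"))
  .reject_non_N(template)
  k <- length(template$degenerate_positions)
  if (k == 0L) return("")
  if (k > 12L) .stopf("refusing to enumerate 4^%d genotypes", k)
  cols <- lapply(seq_len(k), function(j) {
    rep(.BASES, each = 4L^(k - j), times = 4L^(j - 1L))
  })
  do.call(paste0, cols)
}

#' Locate homopolymer runs in phased reads
#'
#' Low-diversity libraries often contain homopolymer stretches (the uncleaved
#' reads of the ribozyme library studied here begin with GGGGG once the TSO
#' anchor abuts the GG transcription start). Because Illumina cluster filters
#' evaluate the first 25 cycles, a long run early in the read is a diversity
#' hazard; phased inserts delay and distribute it. This report composes the
#' uncleaved read for each insert and lists every maximal run of length
#' `>= min_run`, with its cycle position and whether it starts within the
#' first 25 cycles. Runs are scanned over fixed bases only; a randomized (N)
#' position interrupts a run.
#'
#' @param template an [amplicon_template()].
#' @param inserts a [phased_insert_set()], or `NULL` for the unphased read.
#' @param min_run smallest run length to report (>= 2).
#' @param layout a [read_layout()].
#' @return data.frame with columns `insert_id`, `base`, `run_length`,
#'   `start_cycle` (0-based) and `early` (starts before cycle 25).
#' @export
homopolymer_phase_report <- function(template, inserts = NULL, min_run = 5L,
                                     layout = read_layout()) {
  stopifnot(inherits(template, "amplicon_template"), min_run >= 2)
  ctx <- .read_context(template, layout, "uncleaved")
  ins_seq <- if (is.null(inserts)) "" else inserts$inserts
  ins_id <- if (is.null(inserts)) "none" else inserts$ids
  out <- list()
  for (i in seq_along(ins_seq)) {
    read <- substr(paste0(ins_seq[i], ctx), 1L, layout$read_length)
    chars <- strsplit(read, "")[[1]]
    r <- rle(chars)
    stop_at <- cumsum(r$lengths)
    keep <- r$lengths >= min_run & r$values %in% .BASES
    if (any(keep)) {
      start0 <- (stop_at - r$lengths)[keep]  # 0-based cycle of run start
      out[[length(out) + 1L]] <- data.frame(
        insert_id = ins_id[i],
        base = r$values[keep],
        run_length = r$lengths[keep],
        start_cycle = start0,
        early = start0 < 25L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(insert_id = character(), base = character(),
                      run_length = integer(), start_cycle = integer(),
                      early = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read or write an amplicon template (FASTA + YAML sidecar)
#'
#' The sequence travels as FASTA; `cleavage_site` (0-based), the linker and
#' the construct name travel in a YAML sidecar so that coordinates are
#' explicit and versionable.
#'
#' @param template an [amplicon_template()].
#' @param fasta_path FASTA file with one record.
#' @param meta_path YAML sidecar (`name`, `cleavage_site`, `linker`).
#' @return `read_template()` returns an [amplicon_template()];
#'   `write_template()` returns the template invisibly.
#' @export
write_template <- function(template, fasta_path, meta_path) {
  stopifnot(inherits(template, "amplicon_template"))
  dss <- Biostrings::DNAStringSet(template$sequence)
  names(dss) <- template$name
  Biostrings::writeXStringSet(dss, fasta_path)
  yaml::write_yaml(
    list(name = template$name,
         cleavage_site = template$cleavage_site,
         linker = template$linker,
         coordinates = "0-based"),
    meta_path
  )
  invisible(template)
}

#' @rdname write_template
#' @export
read_template <- function(fasta_path, meta_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) != 1L) .stopf("expected exactly one template record, found %d", length(dss))
  meta <- yaml::read_yaml(meta_path)
  amplicon_template(
    name = meta$name %||% names(dss)[1],
    sequence = as.character(dss[[1]]),
    cleavage_site = meta$cleavage_site,
    linker = meta$linker %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
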