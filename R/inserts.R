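#' A set of phased inserts
#'
#' Phased inserts are short fixed sequences of pairwise-distinct lengths,
#' placed at the start of each read so that otherwise identical amplicons are
#' sequenced out of register. Distinct lengths are what creates the phasing;
#' prefix-freeness is what makes demultiplexing unambiguous. The anchor is
#' the fixed sequence (default `"GGG"`, from the template-switching oligo's
#' riboguanosines) that follows every insert in a read.
#'
#' @param inserts character vector of ACGT insert sequences. They are stored
#'   sorted by increasing length; lengths must be pairwise distinct.
#' @param proportions mixing fractions, one per insert (default equal); must
#'   sum to 1 within 1e-9.
#' @param anchor fixed sequence following every insert.
#' @param ids insert identifiers (default `ins<length>`).
#' @return An object of class `phased_insert_set` with fields `inserts`,
#'   `proportions`, `anchor`, `ids`, `lengths`.
#' @examples
#' phased_insert_set(c("ACGT", "CA", "GACCAT"))
#' @export
phased_insert_set <- function(inserts, proportions = NULL, anchor = "GGG",
                              ids = NULL) {
  stopifnot(is.character(inserts), length(inserts) >= 1L)
  for (s in inserts) .check_dna(s, "insert", alphabet = .BASES)
  if (nzchar(anchor)) .check_dna(anchor, "anchor", alphabet = .BASES)
  lens <- nchar(inserts)
  if (anyDuplicated(lens)) .stopf("insert lengths must be pairwise distinct (phasing requirement)")
  ord <- order(lens)
  inserts <- inserts[ord]
  lens <- lens[ord]
  if (is.null(ids)) ids <- paste0("ins", lens) else ids <- as.character(ids)[ord]
  if (anyDuplicated(ids)) .stopf("insert ids must be unique")
  if (is.null(proportions)) {
    proportions <- rep(1 / length(inserts), length(inserts))
  } else {
    stopifnot(is.numeric(proportions), length(proportions) == length(inserts))
    proportions <- proportions[ord]
  }
  if (any(proportions < 0)) .stopf("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    .stopf("proportions must sum to 1 (got %.12f)", sum(proportions))
  }
  # prefix-freeness: with distinct sorted lengths only a shorter insert can
  # be a prefix of a longer one
  for (i in seq_along(inserts)) {
    for (j in seq_along(inserts)) {
      if (i < j && startsWith(inserts[j], inserts[i])) {
        .stopf("insert '%s' is a prefix of '%s'; demultiplexing would be ambiguous",
               ids[i], ids[j])
      }
    }
  }
  structure(
    list(inserts = inserts, proportions = proportions, anchor = anchor,
         ids = ids, lengths = lens),
    class = "phased_insert_set"
  )
}

#' @export
print.phased_insert_set <- function(x, ...) {
  cat("Phased insert set (anchor ", x$anchor, "):\n", sep = "")
  for (i in seq_along(x$inserts)) {
    cat(sprintf("  %-8s %2d nt  %.3f  %s\n", x$ids[i], x$lengths[i],
                x$proportions[i], x$inserts[i]))
  }
  invisible(x)
}

#' Read or write a phased insert set as TSV
#'
#' Columns `insert_id`, `sequence`, `proportion`; the anchor is carried in a
#' `# anchor: <seq>` comment on the first line.
#'
#' @param inserts a [phased_insert_set()].
#' @param path TSV file path.
#' @return `read_inserts()` returns a [phased_insert_set()].
#' @export
write_inserts <- function(inserts, path) {
  stopifnot(inherits(inserts, "phased_insert_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# anchor: ", inserts$anchor), con)
  utils::write.table(
    data.frame(insert_id = inserts$ids, sequence = inserts$inserts,
               proportion = inserts$proportions),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(inserts)
}

#' @rdname write_inserts
#' @export
read_inserts <- function(path) {
  first <- readLines(path, n = 1L)
  anchor <- if (startsWith(first, "# anchor:")) trimws(sub("^# anchor:", "", first)) else "GGG"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  phased_insert_set(df$sequence, proportions = df$proportion, anchor = anchor,
                    ids = df$insert_id)
}
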