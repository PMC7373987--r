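# internal helpers shared across modules

.BASES <- c("A", "C", "G", "T")
.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.check_dna <- function(seq, what, alphabet = .IUPAC) {
  if (!.is_string(seq)) .stopf("%s must be a single character string", what)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    .stopf("%s contains non-IUPAC character '%s' at position %d (0-based %d)",
           what, chars[bad[1]], bad[1], bad[1] - 1L)
  }
  invisible(chars)
}

# per-position mismatch count of each read prefix against a short pattern.
# `ignore` marks pattern positions treated as wildcards (degenerate bases).
# Vectorised over reads; loops only over the (short) pattern.
.prefix_mismatches <- function(reads, pattern, ignore = NULL) {
  L <- nchar(pattern)
  mm <- integer(length(reads))
  short <- nchar(reads) < L
  for (i in seq_len(L)) {
    if (!is.null(ignore) && ignore[i]) next
    p <- substr(pattern, i, i)
    mm <- mm + (substr(reads, i, i) != p)
  }
  mm[short] <- NA_integer_
  mm
}

# n random bases as a character vector (uses the current RNG stream)
.rand_bases <- function(n) .BASES[sample.int(4L, n, replace = TRUE)]

# n random iid-uniform sequences of width w
.rand_seqs <- function(n, w) {
  if (n == 0L) return(character(0))
  cols <- vector("list", w)
  for (j in seq_len(w)) cols[[j]] <- .rand_bases(n)
  do.call(paste0, cols)
}
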