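#' Shannon entropy of a base-composition vector
#'
#' `H = -sum(p_i * log2(p_i))` over the four canonical bases, in bits;
#' terms with `p_i = 0` contribute 0. A perfectly balanced position has
#' H = 2 bits; a constant position has H = 0.
#'
#' @param p numeric vector of 4 base proportions (A, C, G, T); must be
#'   non-negative and sum to 1 within `1e-6`.
#' @return Entropy in bits, in `[0, 2]`.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2
#' shannon_entropy(c(1, 0, 0, 0)) # 0
#' @export
shannon_entropy <- function(p) {
  stopifnot(is.numeric(p), length(p) == 4L)
  if (any(p < 0)) .stopf("base proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) .stopf("base proportions must sum to 1 (got %.8f)", sum(p))
  p <- p[p > 0]
  -sum(p * log2(p))
}

.new_freq_matrix <- function(m, n_reads = NA_integer_) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  colnames(m) <- .BASES
  rownames(m) <- NULL
  if (any(m < -1e-12)) .stopf("negative base proportion")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9)) {
    .stopf("row %d of the frequency matrix sums to %.12f, not 1", which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  }
  structure(m, n_reads = n_reads, class = c("freq_matrix", "matrix"))
}

#' Per-cycle base frequencies of a read collection
#'
#' Counts A/C/G/T at each cycle across reads of a common length and converts
#' to proportions. Ambiguous bases (e.g. N calls) are excluded from that
#' cycle's count, with renormalization over the remaining reads.
#'
#' @param reads character vector of equal-length reads (or a
#'   `Biostrings::DNAStringSet`).
#' @param read_length expected read length; reads of any other length are an
#'   error.
#' @return A `read_length` x 4 matrix of class `freq_matrix` (columns
#'   A, C, G, T; attribute `n_reads`).
#' @export
freq_matrix_from_reads <- function(reads, read_length = 150L) {
  if (is.character(reads)) {
    if (!length(reads)) .stopf("no reads")
    w <- unique(nchar(reads))
    if (length(w) != 1L || w != read_length) {
      .stopf("reads must all have length %d (found lengths: %s)",
             read_length, paste(sort(w), collapse = ", "))
    }
    reads <- Biostrings::DNAStringSet(reads)
  }
  stopifnot(methods::is(reads, "DNAStringSet"))
  counts <- Biostrings::consensusMatrix(reads, baseOnly = TRUE)
  counts <- t(counts[.BASES, , drop = FALSE])
  tot <- rowSums(counts)
  if (any(tot == 0)) .stopf("cycle %d has no unambiguous base calls", which(tot == 0)[1])
  .new_freq_matrix(counts / tot, n_reads = length(reads))
}

#' Exact per-cycle base frequencies of a read-class mixture
#'
#' The analytic counterpart of a read simulation: each component is one read
#' class (e.g. one insert-length x cleavage-state combination) given as its
#' composed read sequence with `N` at randomized positions, plus its mixture
#' proportion. At each cycle a fixed base contributes an indicator and an `N`
#' contributes 1/4 to every base; rows are the proportion-weighted sums.
#' No sampling is involved, so this serves as the exact oracle that
#' Monte-Carlo simulations converge to.
#'
#' @param components data.frame with columns `sequence` (length >=
#'   `read_length`, ACGT or N) and `proportion` (summing to 1), e.g. from
#'   [read_components()].
#' @param read_length cycles per read.
#' @return A `freq_matrix`.
#' @export
analytic_freq_matrix <- function(components, read_length = 150L) {
  stopifnot(is.data.frame(components),
            all(c("sequence", "proportion") %in% names(components)))
  props <- components$proportion
  if (abs(sum(props) - 1) > 1e-9) .stopf("component proportions must sum to 1")
  m <- matrix(0, nrow = read_length, ncol = 4L, dimnames = list(NULL, .BASES))
  for (i in seq_len(nrow(components))) {
    s <- components$sequence[i]
    if (nchar(s) < read_length) {
      .stopf("component %d is shorter (%d nt) than the read length %d; extend the layout pad",
             i, nchar(s), read_length)
    }
    chars <- strsplit(substr(s, 1L, read_length), "")[[1]]
    bad <- !chars %in% c(.BASES, "N")
    if (any(bad)) .stopf("component %d contains unsupported code '%s'", i, chars[bad][1])
    isN <- chars == "N"
    if (any(isN)) m[isN, ] <- m[isN, ] + props[i] * 0.25
    fixed <- which(!isN)
    if (length(fixed)) {
      idx <- cbind(fixed, match(chars[fixed], .BASES))
      m[idx] <- m[idx] + props[i]
    }
  }
  .new_freq_matrix(m)
}

#' Enumerate the read classes of a library configuration
#'
#' Composes, for every insert (or the unphased read) and cleavage state, the
#' full read sequence `insert + anchor + template[..] + linker + pad`
#' truncated at the read length, with `N` preserved at randomized positions,
#' together with its mixture proportion. This is the shared front end of
#' [analytic_freq_matrix()] and [simulate_run()].
#'
#' @param template an [amplicon_template()].
#' @param inserts a [phased_insert_set()] or `NULL` (single unphased class).
#' @param layout a [read_layout()].
#' @param cleaved_fraction probability mass on the cleaved read class
#'   (default 0: all reads carry the full transcript, mirroring a simulation
#'   of the library's uncleaved architecture).
#' @return data.frame with columns `insert_id`, `class`, `sequence`,
#'   `proportion`.
#' @export
read_components <- function(template, inserts = NULL, layout = read_layout(),
                            cleaved_fraction = 0) {
  stopifnot(inherits(template, "amplicon_template"),
            cleaved_fraction >= 0, cleaved_fraction <= 1)
  ins_seq <- if (is.null(inserts)) "" else inserts$inserts
  ins_id <- if (is.null(inserts)) "none" else inserts$ids
  ins_prop <- if (is.null(inserts)) 1 else inserts$proportions
  anchor_ok <- is.null(inserts) || identical(inserts$anchor, layout$anchor)
  if (!anchor_ok) .stopf("insert set anchor (%s) disagrees with layout anchor (%s)",
                         inserts$anchor, layout$anchor)
  classes <- c(uncleaved = 1 - cleaved_fraction, cleaved = cleaved_fraction)
  classes <- classes[classes > 0]
  out <- list()
  for (cl in names(classes)) {
    ctx <- .read_context(template, layout, cl)
    for (i in seq_along(ins_seq)) {
      s <- paste0(ins_seq[i], ctx)
      if (nchar(s) < layout$read_length) {
        .stopf("%s read with insert '%s' spans only %d of %d cycles; extend the layout pad",
               cl, ins_id[i], nchar(s), layout$read_length)
      }
      out[[length(out) + 1L]] <- data.frame(
        insert_id = ins_id[i], class = cl,
        sequence = substr(s, 1L, layout$read_length),
        proportion = ins_prop[i] * classes[[cl]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' PhiX admixture model
#'
#' The default approximates PhiX fragments by iid uniform random bases; the
#' `genome` mode samples read-length windows (either strand) from a supplied
#' genome sequence instead.
#'
#' @param fraction fraction of reads that are PhiX, in `[0, 1]`.
#' @param mode `"iid"` (default) or `"genome"`.
#' @param genome genome sequence (ACGT string), required for `mode = "genome"`.
#' @return An object of class `phix_model`.
#' @export
phix_model <- function(fraction, mode = c("iid", "genome"), genome = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (fraction < 0 || fraction > 1) .stopf("PhiX fraction must be in [0, 1]")
  if (mode == "genome") {
    if (is.null(genome)) .stopf("genome mode requires a genome sequence")
    .check_dna(genome, "PhiX genome", alphabet = .BASES)
  }
  structure(list(fraction = fraction, mode = mode, genome = genome),
            class = "phix_model")
}

.as_phix <- function(phix) {
  if (is.null(phix)) return(phix_model(0))
  if (inherits(phix, "phix_model")) return(phix)
  phix_model(phix)
}

#' Mix a frequency matrix with PhiX
#'
#' In iid mode every row becomes `(1 - f) * row + f * (1/4, 1/4, 1/4, 1/4)`;
#' in genome mode the uniform vector is replaced by the genome's strand-
#' symmetric overall base composition (fragments sample both strands
#' uniformly, so per-cycle composition is the stationary composition).
#'
#' @param m a `freq_matrix`.
#' @param phix a [phix_model()] or a bare fraction.
#' @return The mixed `freq_matrix`.
#' @export
mix_with_phix <- function(m, phix) {
  stopifnot(inherits(m, "freq_matrix"))
  phix <- .as_phix(phix)
  f <- phix$fraction
  q <- if (phix$mode == "genome") {
    comp <- table(factor(strsplit(phix$genome, "")[[1]], levels = .BASES))
    comp <- comp / sum(comp)
    (comp + rev(comp)) / 2  # strand symmetry: A<->T, C<->G
  } else rep(0.25, 4L)
  .new_freq_matrix((1 - f) * unclass(m) + f * matrix(as.numeric(q), nrow(m), 4L, byrow = TRUE),
                   n_reads = attr(m, "n_reads"))
}

#' Per-cycle entropy profile of a frequency matrix
#'
#' @param m a `freq_matrix`.
#' @return An object of class `entropy_profile`: `H` (bits per cycle),
#'   `mean`, `sd` (population SD across cycles), `n_positions`, `n_reads`.
#' @export
entropy_profile <- function(m) {
  stopifnot(inherits(m, "freq_matrix"))
  H <- apply(unclass(m), 1L, shannon_entropy)
  structure(
    list(H = H, mean = mean(H), sd = sqrt(mean((H - mean(H))^2)),
         n_positions = length(H), n_reads = attr(m, "n_reads")),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, digits = 2, ...) {
  cat(sprintf("Entropy profile over %d cycles: %.*f +/- %.*f bits (mean +/- population SD)\n",
              x$n_positions, digits, x$mean, digits, x$sd))
  invisible(x)
}

#' @export
plot.entropy_profile <- function(x, ...) {
  graphics::plot(seq_along(x$H) - 1L, x$H, type = "l", ylim = c(0, 2),
                 xlab = "cycle", ylab = "entropy (bits)", ...)
  graphics::abline(h = c(0, 2), lty = 3, col = "grey")
  invisible(x)
}

#' Serialize or read an entropy profile as TSV
#'
#' Columns: `position` (0-based cycle), `A`, `C`, `G`, `T`, `H`.
#'
#' @param m a `freq_matrix`.
#' @param path output TSV path.
#' @return The data.frame written, invisibly.
#' @export
write_entropy_tsv <- function(m, path) {
  stopifnot(inherits(m, "freq_matrix"))
  prof <- entropy_profile(m)
  df <- data.frame(position = seq_len(nrow(m)) - 1L, unclass(m)[, .BASES],
                   H = prof$H)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Simulate a sequencing run of a library configuration
#'
#' Draws `n_reads` reads from the read-class mixture of
#' [read_components()], replacing each randomized (`N`) position by an
#' independent uniform base, and replacing a `phix` fraction of reads by
#' PhiX reads (iid uniform bases, or genome windows in genome mode).
#' Base-call errors and qualities are the synthetic-data generator's job
#' ([generate_run()]); this simulation targets composition only.
#'
#' @param template an [amplicon_template()].
#' @param inserts a [phased_insert_set()] or `NULL`.
#' @param layout a [read_layout()].
#' @param phix a [phix_model()] or bare fraction (default 0).
#' @param cleaved_fraction probability a read is the cleaved class.
#' @param n_reads number of reads.
#' @param seed mandatory integer seed; identical seeds give identical reads.
#' @return Character vector of `n_reads` reads of `layout$read_length` bases.
#' @export
simulate_run <- function(template, inserts = NULL, layout = read_layout(),
                         phix = 0, cleaved_fraction = 0, n_reads, seed) {
  if (missing(seed)) .stopf("simulate_run() requires an explicit seed")
  stopifnot(n_reads >= 1)
  n_reads <- as.integer(n_reads)
  phix <- .as_phix(phix)
  comp <- read_components(template, inserts, layout, cleaved_fraction)
  set.seed(seed)
  probs <- comp$proportion * (1 - phix$fraction)
  probs <- c(probs, phix = phix$fraction)
  idx <- sample.int(length(probs), n_reads, replace = TRUE, prob = probs)
  reads <- character(n_reads)
  W <- layout$read_length
  for (i in seq_len(nrow(comp))) {
    sel <- which(idx == i)
    if (!length(sel)) next
    reads[sel] <- .instantiate_component(comp$sequence[i], length(sel))
  }
  selp <- which(idx == length(probs))
  if (length(selp)) {
    reads[selp] <- if (phix$mode == "genome") {
      .sample_genome_reads(phix$genome, length(selp), W)
    } else {
      .rand_seqs(length(selp), W)
    }
  }
  reads
}

# draw n concrete reads from one IUPAC component sequence (N -> uniform base)
.instantiate_component <- function(sequence, n) {
  chars <- strsplit(sequence, "")[[1]]
  dp <- which(chars == "N") - 1L
  if (!length(dp)) return(rep(sequence, n))
  chunks <- .split_at_positions(sequence, dp)
  parts <- vector("list", 2L * length(dp) + 1L)
  for (j in seq_along(dp)) {
    parts[[2L * j - 1L]] <- chunks[j]
    parts[[2L * j]] <- .rand_bases(n)
  }
  parts[[2L * length(dp) + 1L]] <- chunks[length(dp) + 1L]
  do.call(paste0, parts)
}

.sample_genome_reads <- function(genome, n, w) {
  G <- nchar(genome)
  if (G < w) .stopf("PhiX genome (%d nt) shorter than the read length %d", G, w)
  starts <- sample.int(G - w + 1L, n, replace = TRUE)
  reads <- substring(genome, starts, starts + w - 1L)
  rc <- sample.int(2L, n, replace = TRUE) == 2L
  if (any(rc)) {
    reads[rc] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[rc])))
  }
  reads
}

#' Early-cycle entropy summary for cluster-filter risk
#'
#' Illumina cluster evaluation uses the first ~25 cycles to filter out low
#' quality clusters, so low-entropy cycles inside that window are where a
#' low-diversity library loses reads. Reports the entropy over the leading
#' window and flags cycles below a threshold.
#'
#' @param profile an [entropy_profile()].
#' @param window number of leading cycles (default 25).
#' @param threshold flag cycles with `H < threshold` (bits, default 1).
#' @return List with `window`, `min`, `mean`, `H` (per-cycle entropy over the
#'   window) and `flagged_cycles` (0-based cycles below threshold).
#' @export
filter_window_summary <- function(profile, window = 25L, threshold = 1.0) {
  stopifnot(inherits(profile, "entropy_profile"))
  if (window > profile$n_positions) {
    .stopf("window (%d) exceeds the profile length (%d)", window, profile$n_positions)
  }
  h <- profile$H[seq_len(window)]
  list(window = as.integer(window), min = min(h), mean = mean(h), H = h,
       flagged_cycles = which(h < threshold) - 1L)
}
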