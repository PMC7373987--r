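# w values by genotype from a genotype_table or a named numeric vector
.w_lookup <- function(x) {
  if (inherits(x, "genotype_table") || (is.data.frame(x) && all(c("genotype", "w") %in% names(x)))) {
    stats::setNames(x$w, x$genotype)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    .stopf("expected a genotype table or a named numeric genotype->w vector")
  }
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Single- and double-mutant activity matrix around a reference genotype
#'
#' The six randomized positions form two 3-nt halves of a pseudoknot
#' (genotype positions 1-3 pair antiparallel with positions 6-4). Relative
#' to the reference genotype this yields 18 single mutants (6 positions x 3
#' alternative bases) and a 9 x 9 double-mutant grid (one mutation in each
#' half). Rows are half-A mutations; columns are half-B mutations ordered as
#' the image of the rows under the pairing map, so the grid diagonal holds
#' the compensatory double mutants that restore a Watson-Crick pair.
#' Genotypes absent from the table are `NA` (missing), never zero. Every
#' cell is a pure lookup of the table's `w` for that genotype.
#'
#' @param table a `genotype_table` (or named genotype->w vector).
#' @param reference reference genotype (6-mer over ACGT).
#' @return Object of class `mutant_activity_matrix`: `reference`,
#'   `reference_w`, `singles` (data.frame: position, ref_base, alt_base,
#'   label, genotype, w), `doubles` (9 x 9 named matrix of w),
#'   `doubles_genotype` (matching genotype matrix).
#' @examples
#' w <- c(CCCGGG = 0.9, GCCGGC = 0.8, ACCGGG = 0.1)
#' m <- mutant_matrix(w, "CCCGGG")
#' m$doubles["C1G", "G6C"]  # compensatory pair, 0.8
#' @export
mutant_matrix <- function(table, reference) {
  w <- .w_lookup(table)
  if (!.is_string(reference) || nchar(reference) != 6L ||
      grepl("[^ACGT]", reference)) {
    .stopf("reference must be a 6-mer over ACGT")
  }
  ref <- strsplit(reference, "")[[1]]
  getw <- function(g) if (g %in% names(w)) unname(w[g]) else NA_real_
  mutate <- function(pos, alt) {
    g <- ref; g[pos] <- alt; paste(g, collapse = "")
  }
  # 18 single mutants
  singles <- do.call(rbind, lapply(1:6, function(p) {
    alts <- setdiff(.BASES, ref[p])
    data.frame(position = p, ref_base = ref[p], alt_base = alts,
               label = paste0(ref[p], p, alts),
               genotype = vapply(alts, function(a) mutate(p, a), ""),
               stringsAsFactors = FALSE)
  }))
  singles$w <- vapply(singles$genotype, getw, numeric(1), USE.NAMES = FALSE)
  rownames(singles) <- NULL
  # 9 x 9 double grid: rows = half A (positions 1-3), columns = half B,
  # column j = pairing-partner of row j (position 7-p, complementary base)
  rows <- singles[singles$position <= 3L, ]
  col_pos <- 7L - rows$position
  col_alt <- unname(.COMPLEMENT[rows$alt_base])
  col_label <- paste0(ref[col_pos], col_pos, col_alt)
  doubles <- matrix(NA_real_, 9L, 9L, dimnames = list(rows$label, col_label))
  dg <- matrix(NA_character_, 9L, 9L, dimnames = dimnames(doubles))
  for (i in 1:9) {
    for (j in 1:9) {
      g <- ref
      g[rows$position[i]] <- rows$alt_base[i]
      g[col_pos[j]] <- col_alt[j]
      dg[i, j] <- paste(g, collapse = "")
      doubles[i, j] <- getw(dg[i, j])
    }
  }
  structure(
    list(reference = reference, reference_w = getw(reference),
         singles = singles, doubles = doubles, doubles_genotype = dg),
    class = "mutant_activity_matrix"
  )
}

#' @export
print.mutant_activity_matrix <- function(x, ...) {
  cat("Mutant activity matrix around", x$reference,
      sprintf("(w = %s)\n", format(x$reference_w, digits = 3)))
  cat(" singles measured:", sum(!is.na(x$singles$w)), "/ 18;",
      "doubles measured:", sum(!is.na(x$doubles)), "/ 81\n")
  invisible(x)
}

#' @export
plot.mutant_activity_matrix <- function(x, main = NULL, ...) {
  m <- x$doubles[nrow(x$doubles):1, , drop = FALSE]
  graphics::image(seq_len(9), seq_len(9), t(m), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "half-B mutation", ylab = "half-A mutation",
                  main = main %||% paste("fraction cleaved around", x$reference))
  graphics::axis(1, seq_len(9), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(9), rownames(m), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Flatten a mutant matrix to a long table
#'
#' One row per cell (singles, doubles and the reference), suitable for TSV
#' export and heatmap plotting.
#'
#' @param x a [mutant_matrix()] result.
#' @return data.frame with columns `row_mutation`, `col_mutation`,
#'   `genotype`, `w`.
#' @export
mutant_matrix_long <- function(x) {
  stopifnot(inherits(x, "mutant_activity_matrix"))
  singles <- x$singles
  half_a <- singles$position <= 3L
  out <- rbind(
    data.frame(row_mutation = "ref", col_mutation = "ref",
               genotype = x$reference, w = x$reference_w,
               stringsAsFactors = FALSE),
    data.frame(row_mutation = ifelse(half_a, singles$label, "ref"),
               col_mutation = ifelse(half_a, "ref", singles$label),
               genotype = singles$genotype, w = singles$w,
               stringsAsFactors = FALSE),
    data.frame(row_mutation = rep(rownames(x$doubles), times = 9L),
               col_mutation = rep(colnames(x$doubles), each = 9L),
               genotype = as.vector(x$doubles_genotype),
               w = as.vector(x$doubles),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a reference activity table
#'
#' Correlates the activities of a mutant matrix (or any genotype->w mapping)
#' with an external reference table over the genotypes present and
#' non-missing in both (pairwise-complete).
#'
#' @param mine a [mutant_matrix()] result, `genotype_table`, or named
#'   genotype->w vector.
#' @param reference_table named genotype->w vector or data.frame with
#'   `genotype`, `w`.
#' @return List: `r` (Pearson), `n_shared`, `n_excluded` (shared genotypes
#'   dropped for missing w), `genotypes`.
#' @export
correlate_with_reference <- function(mine, reference_table) {
  mw <- if (inherits(mine, "mutant_activity_matrix")) {
    x <- mutant_matrix_long(mine)
    stats::setNames(x$w, x$genotype)
  } else {
    .w_lookup(mine)
  }
  rw <- .w_lookup(reference_table)
  shared <- intersect(names(mw), names(rw))
  ok <- shared[!is.na(mw[shared]) & !is.na(rw[shared])]
  if (length(ok) < 3L) .stopf("need >= 3 shared measured genotypes (got %d)", length(ok))
  a <- as.numeric(mw[ok]); b <- as.numeric(rw[ok])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    .stopf("correlation undefined: zero variance in one of the activity vectors")
  }
  list(r = stats::cor(a, b), n_shared = length(ok),
       n_excluded = length(shared) - length(ok), genotypes = ok)
}

#' Probability of failing to detect a rare sequence
#'
#' With `n` sequencing reads (trials) and a per-read detection probability
#' `P`, the chance that a sequence is never seen is `(1 - P)^n`.
#' `failed_detection_prob_exact()` evaluates the closed form in log space;
#' `failed_detection_prob_mc()` estimates the same probability by Monte
#' Carlo, counting model iterations in which a Binomial(n, P) draw is zero
#' (distributionally identical to n Bernoulli trials, evaluated as a single
#' draw per iteration).
#'
#' @param n number of trials (reads).
#' @param P per-trial detection probability, in `[0, 1]`.
#' @param iterations Monte-Carlo attempts (default 200000).
#' @param seed mandatory integer seed for the Monte-Carlo estimate.
#' @return Probability of zero detections (exact, or MC estimate).
#' @examples
#' failed_detection_prob_exact(689334, 4.45e-6)
#' @export
failed_detection_prob_exact <- function(n, P) {
  stopifnot(n >= 1, P >= 0, P <= 1)
  if (P == 1) return(0)
  exp(n * log1p(-P))
}

#' @rdname failed_detection_prob_exact
#' @export
failed_detection_prob_mc <- function(n, P, iterations = 200000L, seed) {
  if (missing(seed)) .stopf("failed_detection_prob_mc() requires an explicit seed")
  stopifnot(n >= 1, P >= 0, P <= 1, iterations >= 1)
  set.seed(seed)
  mean(stats::rbinom(iterations, size = n, prob = P) == 0L)
}
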