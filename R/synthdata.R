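#' Specification of a ground-truthed synthetic sequencing run
#'
#' Describes everything needed to emit a FASTQ run with known per-read truth:
#' the library construct, the insert set (or none, for the low-diversity
#' control), per-genotype true activities, depth, an iid substitution error
#' rate, PhiX admixture and a constant quality score. Per-genotype
#' activities default to independent Beta(2, 2) draws (mean 1/2, full
#' support, made at generation time from the run seed); a
#' compensatory-structure pattern for activity-matrix exercises is available
#' via [compensatory_activities()].
#'
#' @param template an [amplicon_template()].
#' @param inserts a [phased_insert_set()] or `NULL`.
#' @param layout a [read_layout()].
#' @param n_reads number of reads to emit.
#' @param activities named genotype->w vector in `[0, 1]` covering every
#'   genotype of the template, or `NULL` to draw Beta(2, 2) activities.
#' @param abundances optional named genotype relative abundances (default
#'   uniform).
#' @param error_rate per-base iid substitution probability, in `[0, 0.1]`.
#' @param phix a [phix_model()] or bare fraction.
#' @param quality constant Phred quality for emitted bases (default 37).
#' @param seed mandatory integer seed.
#' @return Object of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(template, inserts = NULL, layout = read_layout(),
                               n_reads, activities = NULL, abundances = NULL,
                               error_rate = 0.001, phix = 0, quality = 37L,
                               seed) {
  if (missing(seed)) .stopf("synthetic_run_spec() requires an explicit seed")
  stopifnot(inherits(template, "amplicon_template"), n_reads >= 1)
  if (error_rate < 0 || error_rate > 0.1) .stopf("error_rate must be in [0, 0.1]")
  if (!is.null(activities)) {
    if (is.null(names(activities)) || any(activities < 0 | activities > 1)) {
      .stopf("activities must be a named vector with values in [0, 1]")
    }
  }
  stopifnot(quality >= 2, quality <= 41)
  structure(
    list(template = template, inserts = inserts, layout = layout,
         n_reads = as.integer(n_reads), activities = activities,
         abundances = abundances, error_rate = error_rate,
         phix = .as_phix(phix), quality = as.integer(quality),
         seed = as.integer(seed)),
    class = "synthetic_run_spec"
  )
}

#' Activity pattern with high compensatory diagonal
#'
#' Assigns every genotype a low baseline activity, the reference genotype
#' and its compensatory double mutants (both halves changed so every
#' pseudoknot pair stays Watson-Crick) a high activity, mimicking the
#' structure a pseudoknot mutation scan produces.
#'
#' @param template an [amplicon_template()] with 6 randomized positions.
#' @param reference reference 6-mer.
#' @param high activity for WC-preserving genotypes (default 0.9).
#' @param low baseline activity (default 0.05).
#' @return Named genotype->w vector over all genotypes.
#' @export
compensatory_activities <- function(template, reference, high = 0.9, low = 0.05) {
  genos <- enumerate_genotypes(template)
  if (nchar(genos[1]) != 6L) .stopf("expected 6 randomized positions")
  w <- stats::setNames(rep(low, length(genos)), genos)
  gm <- do.call(rbind, strsplit(genos, ""))
  wc <- gm[, 1] == .COMPLEMENT[gm[, 6]] &
        gm[, 2] == .COMPLEMENT[gm[, 5]] &
        gm[, 3] == .COMPLEMENT[gm[, 4]]
  w[wc] <- high
  w
}

#' Generate a synthetic FASTQ run with exact truth tables
#'
#' Each read samples a genotype (uniform or per `abundances`), is cleaved
#' with probability equal to that genotype's true activity, picks an insert
#' by the set's proportions, is composed per the read layout, then receives
#' iid substitution errors and constant-quality strings. A PhiX fraction of
#' reads is replaced by iid-uniform (or genome-window) sequences. Identical
#' seeds give byte-identical output.
#'
#' @param spec a [synthetic_run_spec()].
#' @param fastq_path optional path; when given the reads are also written as
#'   FASTQ (`.gz` honoured).
#' @return List of class `synthetic_run`: `reads` (data.frame id, sequence,
#'   quality), `truth` (per read: read_id, insert_id, class, genotype),
#'   `activities` (named true w), `spec`.
#' @export
generate_run <- function(spec, fastq_path = NULL) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  set.seed(spec$seed)
  template <- spec$template
  layout <- spec$layout
  n <- spec$n_reads
  W <- layout$read_length
  genos <- enumerate_genotypes(template)
  acts <- spec$activities
  if (is.null(acts)) {
    acts <- stats::setNames(stats::rbeta(length(genos), 2, 2), genos)
  }
  missing_g <- setdiff(genos, names(acts))
  if (length(missing_g)) .stopf("activities missing for %d genotypes (e.g. %s)",
                                length(missing_g), missing_g[1])
  ab <- if (is.null(spec$abundances)) {
    rep(1 / length(genos), length(genos))
  } else {
    a <- spec$abundances[genos]
    if (anyNA(a)) .stopf("abundances missing for some genotypes")
    a / sum(a)
  }
  is_phix <- stats::runif(n) < spec$phix$fraction
  gidx <- sample.int(length(genos), n, replace = TRUE, prob = ab)
  genotype <- genos[gidx]
  cleaved <- stats::runif(n) < acts[gidx]
  ins_id <- if (is.null(spec$inserts)) rep("none", n) else {
    spec$inserts$ids[sample.int(length(spec$inserts$ids), n, replace = TRUE,
                                prob = spec$inserts$proportions)]
  }
  class <- ifelse(cleaved, "cleaved", "uncleaved")
  class[is_phix] <- "phix"
  genotype[is_phix] <- NA_character_
  ins_id[is_phix] <- NA_character_

  # compose reads group-wise: one template chunk decomposition per
  # (insert, class), genotype bases pasted per read
  dp <- template$degenerate_positions
  cs <- template$cleavage_site
  reads <- character(n)
  groups <- unique(data.frame(ins = ins_id, cl = class,
                              stringsAsFactors = FALSE)[!is_phix, , drop = FALSE])
  for (r in seq_len(nrow(groups))) {
    sel <- which(!is_phix & ins_id == groups$ins[r] & class == groups$cl[r])
    if (!length(sel)) next
    ins_seq <- if (groups$ins[r] == "none") "" else
      spec$inserts$inserts[match(groups$ins[r], spec$inserts$ids)]
    ctx <- .read_context(template, layout, groups$cl[r])
    prefix <- paste0(ins_seq, ctx)
    # genotype slots inside the composed read (0-based)
    shift <- nchar(ins_seq) + nchar(layout$anchor) - if (groups$cl[r] == "cleaved") cs else 0L
    slots <- dp + shift
    chunks <- .split_at_positions(prefix, slots)
    parts <- vector("list", 2L * length(slots) + 1L)
    for (j in seq_along(slots)) {
      parts[[2L * j - 1L]] <- chunks[j]
      parts[[2L * j]] <- substr(genotype[sel], j, j)
    }
    parts[[2L * length(slots) + 1L]] <- chunks[length(slots) + 1L]
    composed <- do.call(paste0, parts)
    if (any(nchar(composed) < W)) {
      .stopf("composed %s read with insert '%s' shorter than %d cycles; extend the layout pad",
             groups$cl[r], groups$ins[r], W)
    }
    reads[sel] <- substr(composed, 1L, W)
  }
  if (any(is_phix)) {
    reads[is_phix] <- if (spec$phix$mode == "genome") {
      .sample_genome_reads(spec$phix$genome, sum(is_phix), W)
    } else {
      .rand_seqs(sum(is_phix), W)
    }
  }
  # iid substitution errors: per-read error counts, then positions;
  # the substituted base is uniform over the three other bases
  if (spec$error_rate > 0) {
    k <- stats::rbinom(n, W, spec$error_rate)
    hit <- which(k > 0L)
    if (length(hit)) {
      rid <- rep(hit, k[hit])              # grouped by read
      pos <- sample.int(W, length(rid), replace = TRUE)
      old <- substr(reads[rid], pos, pos)
      off <- sample.int(3L, length(rid), replace = TRUE)
      new <- .BASES[(match(old, .BASES) - 1L + off) %% 4L + 1L]
      tmp <- reads[hit]
      rid2 <- match(rid, hit)
      occ <- sequence(k[hit])              # occurrence rank within its read
      for (r in seq_len(max(k))) {         # one vectorised pass per rank
        s <- which(occ == r)
        if (!length(s)) next
        i2 <- rid2[s]
        str <- tmp[i2]
        substr(str, pos[s], pos[s]) <- new[s]
        tmp[i2] <- str
      }
      reads[hit] <- tmp
    }
  }
  ids <- sprintf("synth_%07d", seq_len(n))
  out <- list(
    reads = data.frame(id = ids, sequence = reads,
                       quality = strrep(intToUtf8(spec$quality + 33L), W),
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, insert_id = ins_id, class = class,
                       genotype = genotype, stringsAsFactors = FALSE),
    activities = acts,
    spec = spec
  )
  class(out) <- "synthetic_run"
  if (!is.null(fastq_path)) {
    write_fastq(out$reads, fastq_path)
    out$fastq <- fastq_path
  }
  out
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("Synthetic run: %d reads (%d phix), %d genotypes, error rate %g, seed %d\n",
              nrow(x$reads), sum(x$truth$class == "phix"),
              length(x$activities), x$spec$error_rate, x$spec$seed))
  invisible(x)
}

#' Write the truth tables of a synthetic run as TSV
#'
#' @param run a [generate_run()] result.
#' @param truth_path per-read truth TSV.
#' @param activities_path per-genotype true activity TSV.
#' @return The run, invisibly.
#' @export
write_truth <- function(run, truth_path, activities_path = NULL) {
  stopifnot(inherits(run, "synthetic_run"))
  utils::write.table(run$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(activities_path)) {
    utils::write.table(
      data.frame(genotype = names(run$activities), w = unname(run$activities)),
      activities_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(run)
}

#' Expected read depth and zero-read probability
#'
#' Under uniform sampling of `n_genotypes` genotypes by `n_reads` reads, the
#' expected depth per genotype is `n_reads / n_genotypes` and the probability
#' a given genotype receives zero reads is `(1 - 1/n_genotypes)^n_reads`.
#'
#' @param n_reads total reads.
#' @param n_genotypes number of unique genotypes.
#' @return List: `mean_depth`, `zero_read_prob`, `expected_zero_genotypes`.
#' @export
expected_read_depth <- function(n_reads, n_genotypes) {
  stopifnot(n_reads >= 1, n_genotypes >= 1)
  p0 <- if (n_genotypes == 1L) 0 else exp(n_reads * log1p(-1 / n_genotypes))
  list(mean_depth = n_reads / n_genotypes,
       zero_read_prob = p0,
       expected_zero_genotypes = n_genotypes * p0)
}
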