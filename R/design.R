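#' Constraints for phased insert design
#'
#' @param lengths distinct insert lengths; the number of inserts must be a
#'   multiple of four for exact base balance (each base in exactly k/4 inserts
#'   at every balanced cycle). Default `c(9, 12, 15, 18)`.
#' @param balance_window number of leading cycles over which columns must be
#'   exactly balanced; defaults to the shortest insert length. Illumina
#'   cluster identification uses the earliest cycles, so this window is where
#'   balance buys signal diversity.
#' @param max_homopolymer longest identical-base run allowed within an insert.
#' @param forbidden_suffix bases disallowed as an insert's final base
#'   (default `"G"`, so an insert never extends the GGG anchor's run).
#' @param forbidden_prefix bases disallowed as an insert's first base.
#' @param max_restarts bound on rejection-sampling attempts per cycle.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(lengths = c(9L, 12L, 15L, 18L),
                               balance_window = min(lengths),
                               max_homopolymer = 2L,
                               forbidden_suffix = "G",
                               forbidden_prefix = character(0),
                               max_restarts = 10000L) {
  lengths <- as.integer(sort(lengths))
  if (anyDuplicated(lengths)) .stopf("insert lengths must be distinct")
  if (length(lengths) < 4L || length(lengths) %% 4L != 0L) {
    .stopf("exact balance needs the number of inserts to be a positive multiple of 4 (got %d)",
           length(lengths))
  }
  if (balance_window > min(lengths)) {
    .stopf("balance_window (%d) cannot exceed the shortest insert (%d)",
           balance_window, min(lengths))
  }
  stopifnot(max_homopolymer >= 1, max_restarts >= 1)
  structure(
    list(lengths = lengths, balance_window = as.integer(balance_window),
         max_homopolymer = as.integer(max_homopolymer),
         forbidden_suffix = forbidden_suffix,
         forbidden_prefix = forbidden_prefix,
         max_restarts = as.integer(max_restarts)),
    class = "design_constraints"
  )
}

# does appending base b to insert `ins` (character vector) respect the
# homopolymer bound?
.run_ok <- function(ins, b, max_run) {
  L <- length(ins)
  if (L < max_run) return(TRUE)
  !all(ins[(L - max_run + 1L):L] == b)
}

#' Design a column-balanced phased insert set
#'
#' At every cycle of the balance window the k inserts jointly carry each base
#' exactly k/4 times, so an equal-proportion mixture of the inserts has
#' maximal (2-bit) nucleotide entropy at each of those cycles. Cycles are
#' filled with random balanced assignments, rejection-sampled against the
#' homopolymer and boundary constraints. Tail cycles of the longer inserts
#' (beyond the window) are chosen greedily to diversify the composed read
#' mixture: at each such cycle the free inserts pick the base that most
#' evens out the weighted base counts contributed by the inserts already
#' reading template context (requires `template`; without one, tails balance
#' against the other tails only).
#'
#' @param constraints a [design_constraints()].
#' @param seed integer seed; the design is deterministic given the seed.
#' @param template optional [amplicon_template()] the inserts will precede;
#'   used only to diversify tail cycles.
#' @param layout a [read_layout()]; supplies the anchor and downstream pad.
#' @return A [phased_insert_set()] with equal proportions.
#' @examples
#' s <- design_phased_inserts(design_constraints(c(1, 2, 3, 4), balance_window = 1), seed = 1)
#' sort(substr(s$inserts, 1, 1))  # A C G T
#' @export
design_phased_inserts <- function(constraints = design_constraints(), seed,
                                  template = NULL, layout = read_layout()) {
  stopifnot(inherits(constraints, "design_constraints"))
  if (missing(seed)) .stopf("design_phased_inserts() requires an explicit seed")
  set.seed(seed)
  lens <- constraints$lengths
  k <- length(lens)
  win <- constraints$balance_window
  maxrun <- constraints$max_homopolymer
  # fixed context (anchor + template + linker + pad) seen by inserts already
  # past their own length, as characters
  full_ctx <- if (!is.null(template)) {
    strsplit(.read_context(template, layout, "uncleaved"), "")[[1]]
  } else character(0)

  ins <- rep(list(character(0)), k)
  # balanced leading cycles
  for (cyc in 0:(win - 1L)) {
    assigned <- FALSE
    for (try in seq_len(constraints$max_restarts)) {
      perm <- sample(rep(.BASES, k %/% 4L))
      ok <- TRUE
      for (i in seq_len(k)) {
        b <- perm[i]
        if (!.run_ok(ins[[i]], b, maxrun)) { ok <- FALSE; break }
        if (cyc == 0L && b %in% constraints$forbidden_prefix) { ok <- FALSE; break }
        if (lens[i] == cyc + 1L && b %in% constraints$forbidden_suffix) { ok <- FALSE; break }
      }
      if (ok) {
        for (i in seq_len(k)) ins[[i]] <- c(ins[[i]], perm[i])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      .stopf("no balanced assignment satisfying the constraints at cycle %d after %d attempts",
             cyc, constraints$max_restarts)
    }
  }
  # greedy diversity for tail cycles
  if (max(lens) > win) {
    for (cyc in win:(max(lens) - 1L)) {
      w <- stats::setNames(numeric(4L), .BASES)
      for (i in seq_len(k)) {
        if (lens[i] <= cyc && !is.null(template)) {
          pos <- cyc - lens[i] + 1L        # 1-based into anchor+context
          b <- if (pos <= length(full_ctx)) full_ctx[pos] else NA_character_
          if (is.na(b)) next
          if (b == "N") w <- w + 0.25 / k else w[b] <- w[b] + 1 / k
        }
      }
      for (i in seq_len(k)) {
        if (lens[i] > cyc) {
          cand <- .BASES[vapply(.BASES, function(b) .run_ok(ins[[i]], b, maxrun), TRUE)]
          if (lens[i] == cyc + 1L) cand <- setdiff(cand, constraints$forbidden_suffix)
          if (!length(cand)) {
            .stopf("constraints infeasible at tail cycle %d of insert %d", cyc, i)
          }
          best <- cand[w[cand] == min(w[cand])]
          b <- if (length(best) > 1L) sample(best, 1L) else best
          ins[[i]] <- c(ins[[i]], b)
          w[b] <- w[b] + 1 / k
        }
      }
    }
  }
  phased_insert_set(vapply(ins, paste, "", collapse = ""), anchor = layout$anchor)
}

#' Check column balance of an insert set
#'
#' The set is balanced over `window` leading cycles when at every such cycle
#' the proportion-weighted share of each base is exactly 1/4 (for equal
#' proportions and k inserts: each base in exactly k/4 inserts).
#'
#' @param inserts a [phased_insert_set()].
#' @param window number of leading cycles to check; defaults to the shortest
#'   insert length and may not exceed it.
#' @return A list of class `balance_report`: `balanced` (logical),
#'   `per_cycle` (4 x window matrix of weighted base shares),
#'   `first_violation` (0-based cycle, or `NA`).
#' @export
validate_balance <- function(inserts, window = NULL) {
  stopifnot(inherits(inserts, "phased_insert_set"))
  if (is.null(window)) window <- min(inserts$lengths)
  if (window > min(inserts$lengths)) {
    .stopf("window (%d) exceeds the shortest insert (%d)", window, min(inserts$lengths))
  }
  m <- matrix(0, nrow = 4L, ncol = window,
              dimnames = list(.BASES, paste0("cycle", 0:(window - 1L))))
  for (i in seq_along(inserts$inserts)) {
    for (cyc in seq_len(window)) {
      b <- substr(inserts$inserts[i], cyc, cyc)
      m[b, cyc] <- m[b, cyc] + inserts$proportions[i]
    }
  }
  dev <- abs(m - 0.25) > 1e-9
  viol <- which(apply(dev, 2L, any))
  structure(
    list(balanced = length(viol) == 0L,
         per_cycle = m,
         first_violation = if (length(viol)) unname(viol[1]) - 1L else NA_integer_),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(if (x$balanced) "Balanced" else
    sprintf("NOT balanced (first violation at cycle %d)", x$first_violation), "\n")
  print(round(x$per_cycle, 3))
  invisible(x)
}
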