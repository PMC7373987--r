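# Packaged synthetic stand-ins for the twister ribozyme study system.
#
# The real Osa-1-4 construct and TSO insert sequences are not redistributed
# here; these synthetic sequences reproduce the architecture that drives
# every analysis in the package: a 54-nt ribozyme starting GG (T7
# transcription start) so that the TSO anchor creates a GGGGG homopolymer at
# the start of every uncleaved read, cleavage near the 5' end, six fully
# randomized (N) positions in two distal 3-nt halves of the T1 pseudoknot
# whose wild-type pairing is CCC/GGG, a fixed RT-primer linker, a fixed
# adapter-stub pad for trailing cycles, and four 9/12/15/18-nt inserts that
# are exactly base-balanced over the first nine cycles. They were generated
# once, from a fixed seed, and are frozen.

.SYN_TRANSCRIPT <- "GGTTACTGAAACTNNNGCATCCTTCGAGTGTTTCGGACANNNTCGCCATAAACC"
.SYN_LINKER <- "GAGCGGCCAACAAACGTATTAATA"
.SYN_PAD <- "GGTCCTGGCGCCTTTACGGAACACTTTAGACGTTCTATTGGGCAATGATCGGAGAATGCTATAGGGCTAGACCTGATCGT"
.SYN_INSERTS <- c("GTTCCTATT", "AACTAAGCGAAT", "TGAAGGTACTTACAA",
                  "CCGGTCCGACCGTTCCTA")

#' Synthetic twister-like library fixtures
#'
#' A frozen synthetic stand-in for the twister ribozyme library construct
#' and its phased-insert set, reproducing the architecture of the study
#' system (see the package vignette): `synthetic_twister_template()` returns
#' the 54-nt construct with cleavage site at offset 5 and six `N` positions
#' (0-based 13-15 and 39-41; wild-type pseudoknot genotype
#' [synthetic_reference_genotype()], `"CCCGGG"`);
#' `synthetic_phased_inserts()` the four balanced 9/12/15/18-nt inserts in
#' equal proportions behind a `GGG` anchor; `synthetic_read_layout()` the
#' 150-cycle MiSeq-style layout with the fixed adapter-stub pad.
#'
#' @return An [amplicon_template()], [phased_insert_set()], [read_layout()],
#'   or reference genotype string respectively.
#' @examples
#' length(enumerate_genotypes(synthetic_twister_template()))  # 4096
#' @export
synthetic_twister_template <- function() {
  amplicon_template(
    name = "twister-like-synthetic",
    sequence = .SYN_TRANSCRIPT,
    cleavage_site = 5L,
    linker = .SYN_LINKER
  )
}

#' @rdname synthetic_twister_template
#' @export
synthetic_phased_inserts <- function() {
  phased_insert_set(.SYN_INSERTS, anchor = "GGG")
}

#' @rdname synthetic_twister_template
#' @export
synthetic_read_layout <- function() {
  read_layout(read_length = 150L, anchor = "GGG", pad = .SYN_PAD)
}

#' @rdname synthetic_twister_template
#' @export
synthetic_reference_genotype <- function() "CCCGGG"
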