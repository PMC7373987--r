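# small in-code fixtures shared across tests

# 30-nt construct, cleavage at offset 5 (leader GGATT), two randomized
# positions (0-based 10, 11) -> 16 genotypes
small_template <- function() {
  amplicon_template("small", "GGATTCGTACNNGACCTTGAGCATTCGAGT",
                    cleavage_site = 5L, linker = "ACTGAC")
}

small_layout <- function(read_length = 40L) {
  read_layout(read_length, anchor = "GGG",
              pad = "TTGACCATGCTAAGGTCCAATGACCTGCAT")
}

small_inserts <- function() {
  phased_insert_set(c("AC", "CGA", "GTAT", "TAGCA"), anchor = "GGG")
}

# independent per-cycle entropy oracle: tabulate characters by hand
entropy_by_hand <- function(reads, pos) {
  b <- substr(reads, pos, pos)
  p <- as.numeric(table(factor(b, levels = c("A", "C", "G", "T")))) / length(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}
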