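---
title: "Phased inserts for low-diversity amplicon sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased inserts for low-diversity amplicon sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedinserts)
```

## The problem

In vitro selection libraries are diverse in their randomized core but share
fixed primer-binding sequences at both ends. On Illumina instruments the
fixed 5′ end is sequenced first, and the cluster-calling and early-cycle
quality filter (which evaluates roughly the first 25 cycles) rely on
neighbouring clusters emitting *different* signals. A library that is
constant over those cycles is "low diversity" in the instrument's sense no
matter how many variants it contains, and loses clusters at the filter.
Spiking in fragmented PhiX genomic DNA restores diversity at the cost of
the spiked read fraction. Phased inserts — short fixed sequences of
pairwise-distinct lengths ligated or template-switched onto each molecule —
restore diversity without consuming reads, at the cost of read length.

This package models the whole decision quantitatively for a
ribozyme-cleavage assay read architecture and provides the downstream
quantification: per-genotype fraction cleaved from phased 5′-RACE reads.

## Read architecture

Every library read is composed, cycle 0 first, as

```
[phased insert (9/12/15/18 nt)] + GGG + transcript[from] + linker + adapter pad
```

where `GGG` is the read-side image of the template-switching oligo's three
riboguanosines, and `from` is the transcript start for uncleaved molecules
or the cleavage site for cleaved ones (the assayed ribozyme cleaves near
its 5′ end, so cleaved reads lack the short leader). Coordinates are
0-based and half-open throughout; cycle 0 is the first sequenced base.
Templates are stored in transcript orientation; the reverse-complement
template-strand representation used for oligo synthesis is an I/O
conversion, not package state. Reads shorter than the read length continue
deterministically into the linker and then a fixed adapter stub ("pad");
composing a read whose fixed context cannot fill all cycles is an error
rather than a silent truncation, because trailing-cycle entropy depends on
this choice.

## Positional entropy model

At each cycle the base composition across reads is a distribution
$p = (p_A, p_C, p_G, p_T)$ and its Shannon entropy in bits is
$H = -\sum_i p_i \log_2 p_i$ (with $0 \log 0 = 0$), between 0 (constant
cycle) and 2 (perfectly balanced). Two routes produce the per-cycle
profile:

* **Analytic** (`analytic_freq_matrix()`): each read class (insert length ×
  cleavage state) contributes its fixed base as an indicator and each
  randomized position as a uniform $1/4$ vector, weighted by the class
  proportion. This is exact — no sampling.
* **Monte-Carlo** (`simulate_run()` + `freq_matrix_from_reads()`): reads are
  drawn from the same class mixture and tabulated. It converges to the
  analytic matrix; the tests assert agreement of the mean within 0.005 bits
  at $10^6$ reads.

PhiX admixture at fraction $f$ replaces each row by
$(1-f)\,p + f\,q$, with $q$ uniform in the default iid approximation or the
strand-symmetric genome composition when a genome is supplied. The uniform
approximation overstates PhiX's per-cycle entropy slightly (the real genome
is ~45% GC and fragments are finite), which is acceptable here because PhiX
enters only as a comparison condition.

Profile summaries use the **population** SD across the 150 cycles (divide
by $n$, not $n-1$): the profile is the complete population of cycles, not a
sample, and this convention reproduces the control summary exactly
(see below). Printed two-decimal reference values for SDs correspond to
two-decimal truncation of the exact values (0.3919 → 0.39, 0.1973 → 0.19).

For the packaged library the four conditions evaluate to:

```{r conditions}
tpl <- synthetic_twister_template(); ins <- synthetic_phased_inserts()
lay <- synthetic_read_layout()
ctrl <- analytic_freq_matrix(read_components(tpl, NULL, lay), 150)
ph <- analytic_freq_matrix(read_components(tpl, ins, lay), 150)
for (m in list(ctrl, mix_with_phix(ctrl, 0.25), ph, mix_with_phix(ph, 0.25)))
  print(entropy_profile(m), digits = 4)
```

The control mean is exact by construction: six uniformly randomized
positions among 150 cycles give $(6 \times 2)/150 = 0.08$ bits. The
balanced inserts raise each of the first nine cycles to exactly 2 bits and
the whole-read mean to ≈1.5 bits with no PhiX at all.

## Insert design

Exact balance requires the number of inserts to be a multiple of four: at
each cycle of the balance window each base is assigned to exactly $k/4$
inserts. The search is rejection sampling of random balanced column
assignments against three constraints — a maximum homopolymer run within an
insert (default 2), a forbidden final base (default G, so an insert never
extends the GGG anchor's run) and optional forbidden first bases — with
bounded restarts. Tail cycles of the longer inserts (cycles past the
window, which still land inside the instrument's 25-cycle filter window)
are chosen greedily to even out the weighted base counts of the composed
read mixture given the template. Because the window columns are
permutations, all inserts differ at cycle 0, which makes any designed set
prefix-free and demultiplexing unambiguous by construction. Designs are
deterministic given a seed.

Insert lengths default to 9/12/15/18 nt. The shortest length sets the
fully-balanced window; the staggered longer lengths distribute any
template homopolymer (here, the GGGGG formed by the GGG anchor against the
GG transcription start of uncleaved reads) across cycles 9–18 instead of
cycle 0 — `homopolymer_phase_report()` tabulates exactly this.

## Quantification model

Processing is a pure pipeline with conserved counts
(assigned + unassigned + dropped = total, asserted on every run):

1. **Demultiplex**: a read is assigned to the insert with the fewest prefix
   mismatches if within `max_mismatch` (default 0), ties to the longest
   insert; the anchor must match exactly. Inserts are synthetic fixed
   sequences, so a mismatch there indicates a bad read — hence the strict
   default.
2. **Classify**: the trimmed read's prefix is compared over a 10-base probe
   against the transcript start (uncleaved) and the cleavage-site suffix
   (cleaved); randomized template positions are wildcards. Templates whose
   two probes coincide are rejected as undecidable at construction of the
   comparison. An exact mismatch tie (possible only with tolerance > 0) is
   left unassigned rather than guessed.
3. **Count**: per-genotype cleaved/uncleaved counts give
   $w = N_\mathrm{cleaved} / (N_\mathrm{cleaved} + N_\mathrm{uncleaved})$.
   Genotypes with ambiguous base calls are dropped and tallied; unobserved
   genotypes are *absent*, and downstream mutant matrices report them as
   missing (`NA`), never as zero.

No read-level quality filter is applied by default (the assay defines no
such filter); an optional mean-Phred threshold exists for exploration.
Reads are single-end in a fixed orientation, so no reverse-complement
search is performed.

The mutant activity matrix around a reference genotype treats genotype
positions 1–3 and 4–6 as the two pseudoknot halves, pairing position $p$
with $7-p$. Rows are half-A mutations; columns are the rows' images under
the pairing map (partner position, complementary base), so the grid
diagonal holds the compensatory double mutants that restore Watson–Crick
pairs. Correlations with external tables are pairwise-complete Pearson,
with the number of exclusions reported — the handling of missing genotypes
is this package's choice, as no standard exists.

Rare-sequence detection uses the binomial model: with $n$ reads and
per-read detection probability $P$, the zero-detection probability is
$(1-P)^n$, computed in log space; the Monte-Carlo twin draws one
$\mathrm{Binomial}(n, P)$ variate per iteration (distributionally identical
to $n$ Bernoulli draws) and reports the fraction of zero-detection
iterations. $n$ is a free parameter of the model.

## Synthetic data generator

`generate_run()` emulates the study conditions: reads sample a genotype
(uniform by default), cleave with probability equal to that genotype's true
activity, pick an insert by the set proportions, are composed per the read
layout, then receive iid substitution errors and constant quality strings,
with an optional PhiX read fraction. Defaults and their rationale:

* **Activities**: independent Beta(2, 2) draws — full support on $[0, 1]$
  with mass away from the degenerate endpoints, so both read classes are
  exercised for every genotype; a compensatory high-diagonal pattern is
  available for matrix-shaped tests.
* **Error model**: iid substitutions only, default rate $10^{-3}$ per base
  (typical Illumina substitution scale); no indels, since indels inside an
  insert would change its effective length and conflate the error model
  with demultiplexing semantics. Error positions are drawn per read from a
  binomial count; coinciding positions within a read (rare) collapse to
  one substitution.
* **Qualities**: constant Q37, consistent with the high mean qualities of
  well-behaved MiSeq runs; qualities are carried, not modelled.
* **Determinism**: one mandatory seed drives genotype, class, insert, PhiX
  and error draws; identical seeds give byte-identical FASTQ.

What the generator does *not* emulate — instrument optics, cluster
crosstalk, the actual passing-filter mechanism, quality-dependent error
rates, indels, or carry-over between cycles — bounds what passing tests
show: they validate the package's arithmetic and bookkeeping on reads with
exactly the declared structure, not robustness to every artefact of real
flow cells. Instrument outcomes (percent clusters passing filter, quality
score distributions) are consequences of the entropy profile plus
instrument internals and are deliberately not predicted.

## The packaged synthetic library

The real study construct and its oligonucleotides are not redistributed;
the package ships a clearly labelled synthetic stand-in
(`synthetic_twister_template()` and friends, `inst/extdata/synthetic_*`)
generated once from a fixed seed and frozen. It reproduces the features
that drive every computation: 54-nt ribozyme starting GG (so the anchor
creates GGGGG at cycle 0 of unphased uncleaved reads), cleavage offset 5,
six N positions in two distal 3-nt halves (0-based 13–15 and 39–41) whose
wild-type pairing is CCC/GGG, a 24-nt linker, an 80-nt adapter pad, and
four 9/12/15/18-nt inserts exactly balanced over cycles 0–8 with no
homopolymer longer than 2 and no terminal G. Unconstrained bases are
uniform random draws. Quantities that depend only on the architecture
(control means 0.08 and ≈1.03 bits, the 2-bit balanced window, genotype
counts) are exact; quantities that depend on the specific base identities —
chiefly the phased-condition means, ≈1.49 and ≈1.76 bits here — are
architecture-dominated but not identical to any particular real construct,
since a 4-class mixture of a common context offset by multiples of 3
samples that context's local 3-periodic diversity.

## Numerical and scale choices

* Entropy terms with $p_i = 0$ contribute 0; frequency-matrix rows must sum
  to 1 within $10^{-9}$; ambiguous base calls (N) in observed reads are
  excluded from their cycle's count with renormalization.
* Only fully randomized (N) degenerate codes are supported; partially
  degenerate IUPAC codes are rejected by the operations that would need to
  interpret them, since the target library class randomizes completely.
* Simulation sizes in the tests: $10^6$ reads for profile-level agreement
  (mean within 0.005 bits of analytic), $10^4$–$2\times10^5$ reads for
  end-to-end recovery checks, 16-genotype reduced libraries where
  per-genotype depth ≥ 100 matters. These sizes put Monte-Carlo noise well
  below the tolerances being asserted while keeping the default suite
  fast.
* Monte-Carlo detection uses 200,000 iterations by default, putting its
  standard error near $5\times10^{-4}$ at the documented parameter point.

## Known limitations

* Demultiplexing is prefix matching, not alignment: an indel inside an
  insert shifts all downstream cycles and the read is (correctly) lost.
* The analytic entropy model treats cycles independently; it cannot
  express instrument effects that couple cycles.
* `mutant_matrix()` assumes the six randomized positions are two
  antiparallel-paired 3-nt halves; other pairing geometries would need a
  different index map.
* The genome-mode PhiX mixer uses the stationary genome composition for
  the analytic route, exact only in the limit of uniformly placed
  fragments.
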