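---
title: "Analyzing sequence evolution of biased short DNA pools"
author: "poolscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing sequence evolution of biased short DNA pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscape)
```

## The scientific problem

Prebiotically plausible pools of short oligonucleotides are typically
*biased*: one nucleobase is over-represented. When such a pool undergoes
templated, strand-displacing replication — short strands annealing to each
other, a polymerase extending the 3' end 5'→3' with bases complementary to
the template — two things happen at once. At the pool level, complementary
copying pushes the average base fraction toward 0.5, erasing the bias. At
the sequence level, structure *emerges*: the first ~12 nt at the 5' end of
each strand keep the original bias (they are never overwritten), the
segment appended next is *inversely* biased (it is a complementary copy of
a biased template), and the fastest-elongating sequences develop strongly
periodic dimer and trimer motifs.

`poolscape` implements the computational side of this story as a tested
pipeline: read preprocessing, composition maps, periodicity detection,
motif/self-complementarity metrics, stacking-energy comparisons, and
partner-motif combinatorics — plus a synthetic-data generator that
produces pools with all of these signatures under known ground truth, so
the entire pipeline can be exercised and validated without any external
download.

## Preprocessing: trimming and insert extraction

Sequencing reads carry the insert followed by a pyrimidine (CT) tail of at
least 4 nt and the literal adapter `AGAT`, with quality declining toward
the 3' end. Preprocessing is two steps:

1. **Sliding-window quality trimming** (`trim_quality()`): 4-nt windows
   are scanned 5'→3' and the read is cut at the start of the first window
   whose mean Phred quality drops below 20 (mean base-call accuracy 99%,
   since `Q = -10 log10 P`). Reads shorter than the window are judged by
   one window over the whole read. The published description of the
   window direction is ambiguous ("3' to 5'" yet cutting at the leftmost
   base); we adopt the canonical 5'→3' convention of the standard
   sliding-window trimmers, which matches the cut-at-window-start rule.
2. **Insert extraction** (`extract_insert()`): the anchored,
   lookahead-guarded patterns
   `(^[AT]{12,})(?=([CT]{4,}AGAT))` (AT pools; GC and ATGC analogues)
   capture the leading insert with greedy backtracking semantics. This
   simultaneously enforces a minimum insert of 12 nt and restricts binary
   pool analyses to genuinely binary sequences. With a 120-nt read
   length, the longest recoverable insert is 120 − 4 − 4 = 112 nt; longer
   sequences lose their adapter to truncation and drop out of the
   sequenced pool ("left behind" by the capture window).

```{r extraction}
read <- paste0(strrep("AT", 56), "CTCT", "AGAT")   # 120 nt
nchar(extract_insert(read, extraction_rule("AT")))
```

## Composition maps

`summarize_pool()` reports the nucleotide-weighted pool fraction
`f_bar` (total reference-base count over total nucleotides — the quantity
that homogenizes under complementary copying), and
`positional_fractions()` builds the length-stacked positional map: for
every sequence length with at least `min_support` sequences (default 50;
bins below it are suppressed rather than zero-filled, to avoid noisy
tails), the fraction of the reference base at each position 1..L, 5'→3'.
For binary pools the maps for the two bases are exact complements.

## Periodicity: conditional matrices and amplitude spectra

Positional fraction maps average over all sequences of a length and so
cannot reveal *in-strand* correlation. `conditional_matrix()` therefore
estimates, for sequences of one length (default 50),
`M[i, j] = 100 P(base j = ref | base i = ref)` in percent. Periodic
sequence structure appears as diagonal stripes in `M`.

`amplitude_spectrum()` reduces `M` to amplitude versus period:

* each row's diagonal entry (identically 100) is replaced by the row's
  off-diagonal mean — without this the self-term leaks broadband power
  and the random-pool baseline could not equal the pool base fraction;
* the row mean `m_i` is subtracted and the harmonic amplitude at
  frequency `1/p` is estimated by a least-squares cosine + sine fit,
  evaluated directly at arbitrary real periods (so the spectrum is a
  continuous function of period, not just integer DFT bins);
* the reported amplitude is `mean_i(m_i + amplitude_i)`, an *additive*
  convention: an unstructured pool sits at a flat baseline equal to the
  reference-base fraction in percent (50 for unbiased pools), and
  periodic structure appears as spikes above it.

The least-squares formulation matters at `p = 2`, the Nyquist period: the
usual `2/N` DFT normalization double-counts there, whereas the fitted
amplitude equals the true cosine amplitude at every period (a constant
signal gives `A(p) = c` exactly; `y = 50 + 10 cos(pi j)` gives
`A(2) = 60`).

Two finite-sample effects are worth knowing. First, replacing the
diagonal (which sits at the phase peak of any planted cosine) attenuates
a true amplitude `c` to about `c (1 - 2/N)` at interior periods and
`c (1 - 1/N)` at Nyquist; the package's parameter-recovery tests check
against this corrected closed form. Second, the magnitude operation gives
the noise floor a small positive (Rayleigh) bias of a few tenths of a
percent at the default problem size.

`detect_periods()` flags local maxima whose excess over the baseline
exceeds `z` robust SDs (MAD) of the grid excesses. The default `z = 10`
was calibrated on unstructured pools: across seeds the largest null peak
statistic stays below ~7, while planted periodicities score 40–100, so
the operating point separates the regimes with wide margins; peaks closer
than 0.75 nt to a stronger peak are treated as its spectral-leakage
sidelobes. Row averages are unweighted by conditioning support; supports
are reported alongside.

```{r periodicity}
p2 <- inject_signatures(list(c(50, 0.5)), n = 2000,
                        period = list(p = 2, amplitude = 0.2, noise = 0),
                        seed = 7)
sp <- amplitude_spectrum(conditional_matrix(p2, "T", 50))
detect_periods(sp)
```

## Zebraness, self-complementarity, k-mer symmetry

*Zebraness* is the fraction of adjacent base pairs that alternate
(`XY`/`YX` steps); homodimer steps (`XX`/`YY`) are *bulky*. An i.i.d.
pool with reference fraction `f` has expected zebraness `2 f (1 - f)`,
so 0.5 separates alternating-enriched from homodimer-enriched pools.

`longest_self_complementary()` measures the longest region of a strand
that could fold back on itself. The default reading is the longest
common substring of the sequence and its reverse complement — the weakest
interpretation of "longest complementary overlap", with overlapping
self-hits allowed (a perfect zebra run is its own reverse complement and
scores its full length, which is precisely the mechanism that links high
zebraness to high self-complementarity). The stricter fold-back variant
(`variant = "foldback"`) returns the longest hairpin stem
(anti-diagonal run of pairings with disjoint arms); both are exposed
because the exact published algorithm is not available, and both agree
with brute-force oracles on exhaustive small-sequence sets.
`selfcomp_profile()` compares a pool per length against a matched random
pool (same alphabet and length histogram, base fraction 0.50, fixed
documented seed) — the expected self-complementarity in the absence of
any pattern.

`kmer_symmetry()` scores how closely reverse-complementary k-mer pairs
(default k = 4) match in abundance: the mean of
`|n(w) - n(rc(w))| / (n(w) + n(rc(w)))` over proper pairs with nonzero
total. Complementary copying drives this score toward 0.

## Stacking energetics

The embedded nearest-neighbor table (`nn_table()`) carries the ten unique
Watson–Crick dimer-step stacking free energies of the unified DNA
parameter set (ΔG°37, kcal/mol); terminal/initiation penalties are
excluded because the motif comparison uses steps only.
`motif_energies()` compares alternating and homodimer steps:

```{r thermo}
motif_energies()
```

The package reports `delta = dG_zebra - dG_bulky`: the stacking *penalty*
of alternating relative to homodimer steps. For A:T, alternating steps
stack 0.27 kcal/mol more weakly than `AA/TT` — zebra-rich AT duplexes
separate more easily, stay out of overly stable structures, and
re-prime; for G:C the sign flips (−0.36 kcal/mol): there the *bulky*
motifs are the weakly stacking, fast-replicating ones. Note the sign
convention: some summaries label this same +0.27/−0.36 pair as "bulky −
zebra"; the printed step energies fix the arithmetic unambiguously, and
`poolscape` documents its convention explicitly. `stacking_score()` sums
step energies over a full duplex and is invariant under reverse
complementation.

## Periodic partner combinatorics

A k-mer motif `w` either pairs with a distinct reverse complement
(`{w, rc(w)}`, a *pool-templating* class: runs of the two motifs can
prime each other across sequences) or is its own reverse complement (a
*self-templating* singleton). `census()` enumerates the classes — with
motifs taken as written, no rotational identification, which is the
definition under which the binary counts come out as 4 classes for k = 3
(`AAA/TTT`, `AAT/ATT`, `ATA/TAT`, `TAA/TTA`), 6 pairs + 4 singletons for
k = 4, and 16 pairs for k = 5 — and verifies
`2 n_pairs + n_self = |alphabet|^k`.

`periodic_fraction()` connects the census to observed pools. Because a
perfect k-periodic repeat distributes its *overlapping* k-mers evenly
over all k cyclic rotations of its unit, naive k-mer counting can never
see a repeat as "dominated" by one motif class. The implemented rule is
frame-restricted: a sequence joins a class when, in some reading frame,
more than half of its frame-aligned k-mers belong to the class. Repeats
score 1 in their own frame; unstructured sequences score near the
class's share of k-mer space in every frame. Phase-shifted classes of
the same repeat family tie and are resolved by census order
(lexicographic representative) — a labeling convention, not a biological
claim.

## The synthetic-data generator

The generator produces every input the pipeline needs, under fixed seeds
(defaults: generator 1001, simulator 2002, emitter 3003):

* `generate_pool()` draws i.i.d. sequences (default 12-mers) with a
  stated per-position bias `f` — the model of the chemically synthesized
  starting pools. The demo configurations use biases in the 0.6–0.75
  range, the regime of the studied pools.
* `inject_signatures()` plants known ground truth: block biases
  (e.g. a 0.75 head and 0.25 body) and sinusoidal periodic modulation of
  the base probability with per-sequence random phase. For integer
  period `p` and modulation amplitude `a` on the probability scale, the
  conditional-probability spectrum has a closed-form excess of
  `100 a^2 c_p / f` at `p` (with `c_p = 1` for `p = 2`, `1/2` for
  `p >= 3`), which the parameter-recovery tests verify.
* `simulate_replication()` is a deliberately minimal mechanistic toy of
  isothermal strand-displacement replication — complement-copying with
  overlap-gated priming — not a kinetic fit. Each round, a configurable
  fraction (default 0.5) of strands act as primers; a primer anneals
  where its 3'-terminal 4 nt (default) are exactly complementary to an
  internal template site and is extended with the complement of the
  template's 5'-ward remainder; strands of ≥ 24 nt may instead fold back
  (probability 0.2) by annealing that same 3' suffix to a complementary
  site upstream *within the strand*, and copy their own 5' region.
  (Anchoring self-templation at the 3' terminus, rather than at the
  globally maximal fold-back run, is deliberate: extension can only
  proceed from the strand's 3' end.) Candidate sites can optionally be
  Boltzmann-weighted by the stacking energy of the contiguous overlap.
  Strand count is conserved — nucleotides are only appended — and mass
  is non-decreasing, which the property tests assert for every
  configuration.
* `emit_fastq()` writes a pool as sequencing-like reads
  (insert + CT tail + `AGAT`, truncated at 120 nt) with a configurable
  quality plateau, 3' decay, and a fraction of degraded tails.

Two emergent properties of the simulator deserve an honest caveat. The
appended segment of a once-extended strand is a complementary copy of a
biased 12-mer prefix, so its expected reference-base fraction is close
to `1 - f`; it is not *exactly* `1 - f`, because annealing sites are
drawn uniformly over all matching occurrences and run-rich neighborhoods
contain more occurrences, which correlates the copied flanks (measured:
≈ 0.275 rather than 0.30 at `f = 0.70`). And after many rounds the
segment at positions 13–24 mixes first-round extensions (strongly
inverted) with later extensions off partially homogenized templates, so
the aggregate is inverted but attenuated. The tests assert exactly what
the mechanism guarantees: head positions 1–12 keep the initial bias,
positions 13–24 are significantly below 0.5, and the pool average
approaches 0.5.

What the generator does *not* emulate: enzyme kinetics and fidelity,
length-distribution dynamics over incubation time, sequencing error
profiles beyond quality decay, or demultiplexing artifacts. Passing
tests on synthetic pools therefore validate the *analysis* — that each
statistic measures what it claims under known ground truth — not any
quantitative claim about wet-lab rates.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen so
that every stochastic check has comfortable statistical margin: 5,000
sequences for spectra and baselines (binomial SE ≈ 1 percentage point
per matrix entry), 10 seeds for seed-robustness claims, 20 replication
rounds for homogenization, exhaustive enumeration of all 4,096 binary
12-mers for the motif oracles. The full suite runs in a few minutes on
one CPU.

## Known limitations

* The amplitude convention reproduces the published baseline and spike
  behavior, but the original supplementary normalization is not
  available; the convention here is documented and calibrated
  (constant-signal and Nyquist identities) rather than copied.
* `detect_periods()` is tuned for pool-level spectra over the default
  2–10 nt grid; very weak periodicities (excess below ~10 robust SDs of
  the noise floor) require lowering `z` and accepting false-positive
  risk.
* The replication simulator makes no claims about length distributions
  or kinetics; it exists to generate pools carrying the qualitative
  signatures the analysis must detect.
* Thermodynamic folding (loop energies, melting temperatures, salt
  corrections) is out of scope; self-complementarity is sequence-level
  only.
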