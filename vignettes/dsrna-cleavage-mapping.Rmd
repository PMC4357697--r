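---
title: "Mapping the sequence specificity of a dsRNA endonuclease"
author: "dscleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the sequence specificity of a dsRNA endonuclease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscleave)
```

## The problem

Mini-III RNases are homodimeric members of the RNase III superfamily that
consist of the catalytic domain alone, and — unusually for this family —
cleave long, perfectly base-paired double-stranded RNA at preferred
sequences. The *Bacillus subtilis* enzyme strongly prefers duplex sites
whose strands read `ACC^U` and `AGG^U` around the two scissile bonds
(`^` marks the bond), making it a prototype of a sequence-specific dsRNase.
`dscleave` implements the computational side of characterising such an
enzyme:

1. **cut geometry** — the coordinate algebra of staggered duplex cleavage
   with 3' overhangs;
2. **site calling** — turning per-strand counts of mapped fragment 3' ends
   into weighted cleavage-site calls;
3. **motif discovery** — a discriminative IUPAC word search against a
   genomic background, with incremental width selection, and a
   one-occurrence-per-sequence EM that refines a PWM from the most frequent
   end-proximal reads;
4. **saturation-mutagenesis consensus** — tolerated/preferred base sets per
   position from single-substitution relative rates;
5. **kinetics** — initial cleavage rates by linear regression of
   densitometric time courses, normalized across enzymes and substrates;
6. **a synthetic-data generator** that emulates a three-segment
   bacteriophage-like dsRNA genome with a planted preference model, so the
   whole pipeline can be exercised with known ground truth.

## Coordinates and cut geometry

All positions are 1-based and residue-inclusive. A scissile bond is named
by the residue immediately 5' of it, in the numbering of the strand on
which it is named; bottom-strand positions use the bottom strand's own
5'→3' frame, and convert to reference coordinates as `ref = L - pos + 1`.
Making every coordinate's frame explicit removes the ambiguity that
plagues end-mapping bookkeeping.

An enzyme that leaves a 3' overhang of `v` nt and cuts the top strand
after residue `i` cuts the bottom strand after bottom residue
`b = L - i + v`. Overhangs are signed (positive 3', negative 5', zero
blunt), so the same algebra covers other dsRNases at no cost:

```{r geometry}
bottom_bond_from_top(14, length = 30, overhang = 2)  # the classic 14|15 -> 18|19 pair
infer_overhang(14, 18, 30)
```

Primer-extension stops are interpreted conservatively: the strong
termination at template residue `k` marks the cleavage-generated 5' end,
so the bond is `k - 1 | k`; the weaker band one residue further is
attributed to non-templated addition by the reverse transcriptase and
discarded (`termination_to_bond()`).

One known tension in this coordinate bookkeeping: for the classic
mutagenesis substrate the symmetric 14-nt window at positions 83–96 is
consistent with a top-strand bond at 89|90 and an `ACC` ending at residue
89, and that is the convention adopted here (`site_window(seg, 89)` spans
83–96 and a single cut at bond 89 of a 234-bp duplex yields 89/147-nt
products, matching the observed ~90/150 gel bands). User data are never
silently renumbered.

## Site calling from end-capture tracks

End-capture sequencing ligates adapters to the 3' ends of cleavage
products, so mapped read termini mark fragment 3' ends. A staggered cut at
top bond `i` leaves a top-strand 3' end at reference position `i` and a
bottom-strand 3' end at reference position `i - 1` (for a 2-nt 3'
overhang). `call_sites()` therefore pairs the top track at `i` with the
bottom track at `i - 1`, requires at least `min_support` reads on *both*
strands (default 1), and sums the two supports into the site weight.
Segment-terminal end positions are excluded — uncleaved control libraries
put ~93% of their reads there, identifying them as library artifacts
rather than cleavage products; `terminus_fraction()` computes that control
statistic. Adjacent or tied sites are all reported; no peak merging is
performed.

The alternative reading of the pairing rule (both positions in their own
strand's numbering) is rejected: only the reference-coordinate `i` /
`i - 1` pairing is consistent with the 14|15 + 18|19 worked example and a
2-nt 3' overhang.

## Discriminative motif discovery

Positive instances are up-to-14-nt windows centred on called sites, each
carrying its site weight as an integer multiplicity (weights are read
counts). The background is every 14-nt sliding window of the genome, step
1 (`build_background()`). For a fixed width, `discover_motif()` seeds with
every exact word present in the positives (a window counts once per word,
in forward or reverse-complement orientation), ranks seeds by the
one-sided hypergeometric tail — population = positives + background,
draws = positives, successes = windows containing a match — and then
greedily generalizes the best seeds one position at a time to degenerate
IUPAC letters, accepting a step only if the tail probability strictly
improves.

Numerical choices that matter:

* **Log-space ranking.** At realistic depths (weighted positive counts of
  order 10^5) the tail probabilities underflow to exactly zero in double
  precision, which would reduce the ranking to tie-breaks. All ranking is
  done on the natural-log tail probability; `p_value` is reported
  alongside `log_p_value`.
* **No `N` in discovered motifs.** A wildcard position carries no
  discriminative information, and `N`-padded motifs would let the
  incremental width search grow indefinitely at zero cost (every
  `NACCUN`-type motif matches essentially whatever `ACCU` matches).
  Generalization therefore stops at three-base codes. `N` remains legal in
  user-supplied motifs for scanning.
* **Tie-breaks.** Equal log-p motifs are ordered by fewer degenerate
  letters, then lexicographically; seeds are canonicalized to the
  lexicographically smaller of word/reverse-complement when both strands
  are searched.
* **No multiple-testing correction** — the output is a ranking; an
  E-value (p times the number of seeds examined) is reported for context.

### Width selection

The search runs at widths 4–14 (`select_width()`). For the best motif at
each width it records *presence* (weighted fraction of positive windows
matched) and *diversity* (number of distinct exact words matching the
motif in the positives). The chosen width is the largest one whose
presence is at least `tau_p` times the presence at width 4 **and** whose
diversity is at least `tau_d` times the diversity one width earlier — an
operationalization of "the longest motif that does not cause a dramatic
drop in both submotif diversity and motif presence". The published
procedure gives no numeric criterion, so both ratios default to 0.5 and
the full trace is always returned for inspection. On simulated data with
a four-informative-position planted model this selects width 5–6,
mirroring the six-nucleotide optimum reported for the real enzyme.

### PWM refinement by EM

The second route mimics fixed-width motif refinement on the most frequent
unique end reads (`top_unique_reads()`, default n = 200, count-ranked with
lexicographic tie-breaks). `em_pwm()` fits one motif occurrence per
sequence: the E-step computes a posterior over start positions *and
orientations* (motif columns versus uniform 0.25 background), the M-step
re-estimates the PWM from posterior-weighted counts with a 0.25
pseudocount per base. Two details:

* The two-strand E-step is essential, not cosmetic: genomic sites occur in
  both orientations, so the read pool is an `ACCU`/`AGGU` mixture that a
  single-strand EM smears into an uninformative consensus.
* The reported objective is the pseudocount-penalised log-likelihood (data
  log-likelihood plus the Dirichlet smoothing term). That is the quantity
  the pseudocount M-step actually ascends, so it is non-decreasing by the
  EM guarantee; the raw likelihood can decrease by ~1e-6 per iteration
  near convergence.

Initialisation is from the most frequent exact word; five seeded restarts
(jittered starts) are run and the best final objective kept.
`consensus_string()` renders a PWM column as a single base when its
frequency is ≥ 0.5 *and* at least twice the runner-up, as a two-base IUPAC
code when the top two jointly reach 0.8, and as `N` otherwise.

## Saturation mutagenesis

`design_saturation()` builds the full 14-position × 3-substitution = 42
variant panel. `derive_consensus()` declares a base *tolerated* when its
relative cleavage rate (wild type = 1) is at least `theta`; the published
analysis never quantifies its cutoff, so `theta = 0.5` is the default, is
a visible argument, and is recorded in the returned object. The
*preferred* base is the rate argmax (ties go to the wild type). Fully
unconstrained positions render as `N` and are trimmed from the flanks, so
a CC-obligate core with degenerate flanks prints in the standard notation,
e.g. `(G/A/U)(A/U)CC^(U/A)(C/A/U)(G/A/U)`.

## Scanning and in-silico digestion

`scan_duplex()` matches an IUPAC motif (or a PWM with an explicit log-odds
threshold; `pwm_score_threshold()` provides the conventional 80%-of-maximum
choice) on both strands; a bottom-strand match at bottom bond `b` is
canonicalized to top bond `L - b + overhang`. Overlapping matches are all
reported. `insilico_digest()` turns a site list into products, tracking
both strand lengths per product; the apparent gel size of a
staggered-ended product is taken as the longer strand's length, since
overhung duplexes migrate approximately with their total span.
`banding_table()` sorts apparent sizes in gel order above a visibility
cutoff (default 20 nt).

```{r digest}
seg <- make_genome(sim_config(segment_lengths = 234L, seed = 1,
                              planted_per_segment = 0L))$segments[[1]]
insilico_digest(seg, sites = 89)
```

## Kinetics

`initial_rate()` is ordinary least squares of fraction-cleaved against
time. The fit keeps an intercept by default — gel densitometry has
time-zero backgrounds — with `through_origin = TRUE` available; rates come
with standard errors and are normalized for the enzyme amount. Any
fraction above 0.5 triggers a warning that the linear initial-rate
assumption is strained (the assays this models use 15/30/45-min points in
the linear regime). `relative_rates()` and `preference_profile()` express
rates against a reference substrate, per enzyme, so statements like "the
variant site is cleaved 62% slower" or "preference order
pKS-ACCU > NGS-ACCU > NGS-AUCU" are one function call. No significance
testing is attached, and no Michaelis–Menten or biphasic
(specific + nonspecific) model is fitted: only the initial-rate analysis
is in scope.

## The synthetic-data generator

`sim_config()` defaults emulate the study conditions end to end: three
linear segments of 6374, 4063 and 2948 bp; a 10-minute limited digest;
about 2×10^5 sampled fragment ends; and a 7% uniform-breakage background,
the level seen in uncleaved control libraries. Sequences are uniform over
`{A,C,G,U}` except at planted 14-nt windows (about one per 500 nt by
default) drawn from the preference model; ground truth is obtained by
*scanning* both strands for the model's core, so chance `ACCU`/`AGGU`
occurrences are reported alongside the planted sites rather than ignored.

Design choices, made once and documented:

* **First-order cutting.** Each candidate site is cut independently with
  probability `1 - exp(-k_s * m * t)` (`m` = its window multiplier
  product), and every bond nonspecifically with `1 - exp(-k_ns * t)`. No
  rate law is published for this system; the simplest memoryless model is
  used. Defaults `k_s = 0.2 /min` and `k_ns = 1e-6 /bond/min` put planted
  sites near saturation after 10 min while keeping nonspecific breakage at
  the few-per-genome level, qualitatively matching a limited digest.
* **The preference model** assigns multiplier 1 to consensus-tolerated
  bases, 0.05 to disallowed ones, and 0 to substitutions of the obligate
  CC core — the qualitative shape of the single-substitution data, whose
  numeric values are not published.
* **Background breakage** is uniform over bonds and strand-paired with
  the same overhang geometry, giving the site caller a realistic
  false-positive floor.
* **End sampling** is multinomial at fixed expected depth; no
  PCR-duplicate model (the analysis weights by counts, so duplication
  modelling adds nothing testable).
* **End reads.** For each sampled internal end, the emitted 8-nt read is
  the reference top-strand window `[bond - 4, bond + 3]`, which centres
  the tetranucleotide straddling the bond so the read set is closed under
  reverse complement across site orientations. This emulates post-mapping
  extraction of site-spanning tags rather than raw sequencer output: true
  fragment-sense reads from the two strands would be staggered by the
  2-nt overhang, which a width-8 EM on 8-nt reads cannot re-align. This
  idealization is a stated limitation of the generator.
* **Determinism.** All randomness flows from the single config seed
  (stage-specific offsets keep genome, digest and capture independent);
  identical configurations give byte-identical outputs.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing errors and quality, adapter and PCR
bias, reverse-transcription drop-off, RNA secondary structure,
mismatched or bulged duplexes, and the three-way-junction context of the
natural pre-rRNA substrate.

`simulate_satmut_rates()` emits the 42-record table for a planted
consensus with rate 1 for the wild type, 0.8 for tolerated substitutions,
0.05 for disallowed ones (0 at obligate core positions), plus optional
Gaussian noise — calibrated so that `derive_consensus()` at `theta = 0.5`
round-trips exactly at zero noise. `simulate_timecourse()` draws
`clamp(slope * t + N(0, sd), 0, 1)`.

## Problem sizes used by the test suite

The shipped tests run the full default genome for motif recovery (a
20-seed panel at 10^5 sampled ends with a 10% background, requiring the
exact `ACCU`/`AGGU` core as the top motif in at least 19 of 20 seeds),
10^4 digest replicates for the rate-multiplier calibration, 10^3
replicates for slope-estimator calibration, and exhaustive enumeration of
all hypergeometric configurations up to population 12 as the independent
oracle for the enrichment statistic. These sizes were chosen to make the
statistical assertions sharp at interactive runtimes.

## Known limitations

* The discriminative search refines only the top seeds per width (a
  DREME-like heuristic); it is a ranking tool, not an exhaustive motif
  enumerator, and finds one motif per run.
* PWM scanning uses a uniform background; genomes with strong composition
  bias would warrant a composition-matched log-odds background.
* The width-selection thresholds operationalize a qualitative published
  criterion; the full trace is always returned so the choice can be
  audited.
* Apparent gel size = longer strand length is a deliberate simplification
  of overhung-duplex migration.
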