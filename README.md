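# dscleave

Cleavage-site mapping and sequence-specificity analysis for
double-stranded RNA endonucleases.

Mini-III RNases — RNase III-family enzymes reduced to the bare catalytic
domain — cleave long, perfectly base-paired dsRNA and, unlike most of
their relatives, do so with a pronounced sequence preference (the
*Bacillus subtilis* enzyme favours duplex sites reading `ACC^U`/`AGG^U`
around the two scissile bonds, where `^` marks the bond). Characterising
such an enzyme computationally means tying together several pieces of
bookkeeping and statistics that are easy to get subtly wrong: the
coordinate algebra of staggered cuts with 2-nt 3′ overhangs, pairing
fragment 3′-end counts across strands into site calls, discriminative
motif enrichment against a genomic background, consensus derivation from
saturation mutagenesis, and initial-rate kinetics. `dscleave` implements
that pipeline for R, for anyone mapping the specificity of a dsRNA-cleaving
nuclease from end-capture sequencing of limited digests.

## The model in brief

* **Geometry.** A cut after top-strand residue `i` of an `L`-bp duplex by
  an enzyme leaving a 3′ overhang of `v` nt implies a bottom-strand cut
  after bottom residue `b = L − i + v`; conversely `v = i + b − L`. All
  coordinates are 1-based; a bond is named by the residue 5′ of it.
* **Site calling.** A cut at top bond `i` leaves fragment 3′ ends at
  reference positions `i` (top strand) and `i − 1` (bottom strand, 2-nt
  3′ overhang). A site is called iff both strands have ≥ `min_support`
  reads at the paired positions, and the two supports sum to the site
  weight. Segment-terminal ends are excluded (library artifacts, per
  uncleaved controls).
* **Motif discovery.** Weighted site windows (≤ 14 nt) versus all sliding
  14-mers of the genome, scored by the one-sided hypergeometric tail
  `P(X ≥ k)` in log space; exact-word seeds are greedily generalized to
  IUPAC letters, the width 4–14 is chosen as the longest without a
  dramatic drop in presence and submotif diversity, and a
  one-occurrence-per-sequence EM refines a PWM from the top 200 unique
  8-nt end reads.
* **Consensus from mutagenesis.** For each of 14 window positions × 3
  substitutions, a base is tolerated if its relative rate (wild type = 1)
  is ≥ 0.5; preferred = rate argmax. Renders as, e.g.,
  `(G/A/U)(A/U)CC^(U/A)(C/A/U)(G/A/U)`.
* **Kinetics.** Initial rate = OLS slope of fraction-cleaved vs time,
  normalized for enzyme amount; relative rates and per-enzyme substrate
  preference profiles against a reference substrate.

A synthetic-data generator emulates a three-segment bacteriophage-like
dsRNA genome (6374/4063/2948 bp) with a planted positional preference
model, first-order limited digestion, multinomial end capture with a
uniform-breakage background, noisy time courses, and variant rate tables —
so every stage of the pipeline runs against known ground truth. See the
methods vignette (`vignettes/dsrna-cleavage-mapping.Rmd`) for the model
assumptions and design choices.

## Worked example

Simulate a limited digest of the default genome, call sites, and recover
the planted specificity by both routes:

```r
library(dscleave)

cfg     <- sim_config(seed = 1)                 # phage-like 3-segment genome
genome  <- make_genome(cfg)
digest  <- simulate_limited_digest(genome, cfg)
capture <- simulate_end_capture(digest, genome, cfg)

sites <- do.call(rbind, lapply(capture$tracks, function(tr)
  call_sites(tr$top, tr$bottom)))
instances  <- weighted_instances(sites, genome$segments)
background <- build_background(genome$segments)

discover_motif(instances, background, width = 4)[1, c(1, 3, 5, 8)]
#>   motif positive_hits background_hits log_p_value
#> 1  ACCU        178230            1382   -30425.49

em_pwm(top_unique_reads(capture$reads), width = 8, seed = 1)
#> <pwm> width 8, consensus NNACCUNN, total IC 8.92 bits
```

The discriminative search ranks the exact core `ACCU` first by a wide
log-p margin (178,230 of 183,204 weighted site windows contain it, against
1,382 of 13,346 background windows — a 9.4-fold enrichment), and the EM
route independently converges on the same core from the read pool. The
control library statistic behaves like its experimental counterpart:

```r
ctrl <- sim_config(seed = 1, control_mode = TRUE)
g2   <- make_genome(ctrl)
cap2 <- simulate_end_capture(simulate_limited_digest(g2, ctrl), g2, ctrl)
terminus_fraction(cap2$tracks)
#> [1] 0.931
```

i.e. ~93% of reads from an uncleaved library start at one of the six
segment termini (the configured 7% uniform-breakage background accounts
for the rest), whereas digested libraries put nearly all reads at internal
cleavage-generated ends.

Single-site substrates reproduce the expected banding: a 234-bp duplex cut
at bond 89 yields products of apparent size 89 and 147 nt
(`insilico_digest`, `banding_table`), and `derive_consensus` on a
42-variant rate table with an intolerant CC core prints the consensus in
the standard notation shown above.

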