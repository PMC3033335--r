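---
title: "Models and methods for comparative intron-feature analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for comparative intron-feature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `splicescape`, the parameters
that matter, the numerical choices made where the methods left room, and
what the synthetic-data validation does and does not establish about real
data.

## The five features and their scores

An intron is scored on five features, each as a log-odds ("information")
score in bits against a genome-wide background.

**Splice-site and branch-point motifs.** A motif is a column-stochastic
matrix of base frequencies; its log-odds entries are
`log2((f + eps)/(F + eps))` with pseudo count `eps = 1e-4` applied to
both motif and background. The donor window covers positions -3..+6
around the exon-intron junction, the acceptor -13..+1 around the
intron-exon junction; both are built from gap-less junction alignments of
all canonical (GT-AG, GC-AG, AT-AC) introns of a species. Motif
information content is the relative entropy against the background,
computed per column from raw frequencies with the `0 log 0` convention —
this keeps the closed forms exact (2 bits for an invariant column on a
uniform background, 0 when motif equals background) while scoring itself
uses the pseudo-counted log-odds.

**PPT.** Within the 50 nt upstream of the 3' splice site (the terminal
dinucleotide excluded — it belongs to the acceptor motif; the window is
configurable), the tract end is the last pyrimidine dinucleotide. A
running score accumulates +1.0 per C/T and -1.5 per A/G scanning
5'-wards and stops once it falls 2 or more below its running maximum;
the tract start is the position of maximal score, ties resolved to the
5'-most (longest tract; the choice is not observable in the score). An
intron lacks a PPT if no pyrimidine dinucleotide exists or the
candidate tract is under 50% C+T.

**BP.** Candidate 5-mers are scored with a 4 x 5 core matrix (the
package default encodes the canonical CURAY-type core with the branch
adenosine at position 4; any matrix can be substituted as data). The
scan covers 5-mer start positions within 100 nt of the 3' end and
strictly upstream of the PPT start; a 5-mer may overhang into the
tract. This start-position reading matters: the branch motif's final C
is usually absorbed into the detected PPT, and requiring the whole
5-mer upstream of the tract would systematically miss true branch
points. The best 5-mer above 1.85 bits (ties to the 3'-most position,
matching biological branch placement) contributes its heptamer — the
5-mer plus the upstream 2-mer — to the species' 4 x 7 BP profile. By
default no BP is reported without a PPT, on the premise that a
functional branch point is followed by a functional tract; an override
scans the full window.

**Length.** Intron lengths are modelled as a two-component mixture of
three-parameter Frechet laws (shape, scale, location each), fitted by
direct numerical maximum likelihood on unit-interval discretised
masses: Nelder-Mead from several quantile-split initialisations plus
jittered restarts, then a BFGS polish; the restart stream is a private,
fixed RNG so the fit is a deterministic function of the data. The
discrete density is renormalised on `[L_min, L_max)` with `L_min = 30`
and `L_max` the 99% quantile of the longer component, and the score is
`log2(f(l)/c)` against the uniform density `c`. Out-of-range lengths
receive the most-penalised in-range score and a flag. The short-intron
threshold is the 95% quantile of the equal-weight average of the
species' fitted short components; pipelines typically round this to a
fixed cutoff (250 nt for the broad eukaryotic panels this methodology
targets) so that a single range applies across species.

**Composition.** Intron and genome sequences are modelled by
homogeneous fourth-order Markov models, stored as 5-mer joint
distributions (pseudo count 1 per cell) from which all conditionals and
the order-0..3 ramp for a sequence's first four positions are derived by
marginalisation. The score is `(log2 P_I(s) - log2 P_G(s)) / l`, bits
per nucleotide. Genome models are symmetrised over both strands.

## Divergences, trees, discordance

For motifs, the divergence between species A and B sums, over retained
columns and bases, `f log2(fG/(Fg)) + g log2(Fg/(fG))` — the difference
in expected motif score under the cognate versus the heterologous
log-odds. Donor columns +1/+2 and acceptor -2/-1 (the invariant terminal
dinucleotides) are excluded. Frequencies are epsilon-smoothed, so
self-divergence is exactly zero; the measure can be slightly negative
for very close profiles, is reported as-is, and is clipped at zero (with
a warning) only when a matrix enters UPGMA. The composition divergence
applies the same form to the 1024 intronic versus genomic 5-mer
probabilities; the length divergence is the symmetric Kullback-Leibler
divergence of the two discrete densities renormalised on their common
range (without renormalisation the truncated sums would not compare
distributions).

UPGMA is implemented directly so that ties at the minimal distance merge
the lexicographically smallest pair of representative labels — fully
deterministic; it is cross-checked against an independent implementation
on random matrices in the test suite. Tree discordance is the RMSD
between nodal matrices (internal nodes per leaf pair, multifurcations
counting once) averaged over the reference trees; the null permutes the
feature tree's leaf labels on its fixed topology (100 permutations by
default). Both the normal-tail p-value and an exact permutation rank
p-value are reported: 100 permutations can rank an observation but
cannot empirically support astronomically small tails, which only the
normal approximation extrapolates.

## Recognition decomposition

Candidates are all donor/acceptor dinucleotide pairs (GT/GC with AG, AT
with AC) within 100 nt of the true boundaries whose implied length lies
in `[31, 250]` by default (the "typical short intron" range, made
explicit and configurable). Each candidate is scored on the selected
features — BP and PPT recomputed on the candidate's own implied intron,
absence contributing 0 bits — and the argmax is the prediction, ties
broken towards the 5'-most donor then acceptor. `TAc = -log2(1 - Ac)`
is capped at the necessary amount `-log2(0.02)` when `Ac = 1`
(saturation). TAc is measured in base 2 so that contributions and the
deficit are in bits.

Three conventions deserve note. (i) BP, length and composition
contributions are non-negative TAc gains over the 5'ss+3'ss baseline.
(ii) Every evaluated subset contains both splice sites, so their
individual contributions are not identified by subset differences; the
baseline TAc is split between them in proportion to their information
contents. This is a documented convention, not a measurement. (iii) The
deficit in bits is `necessary - max TAc` (floored at 0), but because
feature gains need not add up to the best subset's TAc, the *share*
table defines the deficit share as the residual `1 - sum(feature
shares)` (floored and renormalised at saturation) so that shares always
sum to one.

## The synthetic generator and what the tests show

`generate_species` plants, per species: subtype fractions
(98.6/1.3/0.1% GT-AG/GC-AG/AT-AC by default, the broad-survey average),
donor/acceptor/BP matrices (vertebrate-style defaults; the branch
profile defaults to a strong, fungal-style conserved motif), PPT length
(normal around 18 nt, sd a quarter of the mean) and C+T content (87%) —
mammal-like values — a length mixture (short component: shape 3, scale
40, location 30; long component: shape 2, scale 800, location 2000;
weight 0.8 short, emulating a compact genome), and iid-by-default
Markov models (intron interiors 10 G+C points below the 45% G+C
genome). Intron architecture is donor hexamer, Markov interior, BP
heptamer, PPT, acceptor 13-mer, with subtype dinucleotides overriding
the terminal positions; lengths below 31 nt are resampled. In genome
mode, introns sit in two-exon genes (150 nt exons) separated by 200 nt
spacers on a single contig, on random strands, with 1-based GFF3
emitted next to the FASTA; internal computation is 0-based half-open.
Clades arise by log-space jitter of all planted distributions along a
guide topology whose edge lengths are drift magnitudes.

Validation recovers planted truths in the regimes where they are
statistically identifiable, and the package is explicit about those
regimes:

- Donor and acceptor matrices are recovered to within total variation
  0.02 per column at 20,000 introns under the defaults.
- BP recovery at that tolerance is tested under near-invariant planting
  (column strength 0.995, yeast-like TACTAAC). This is not a loophole
  but a property of scan-based BP detection: when the planted motif is
  soft, true sites drawn with off-consensus bases are out-scored by
  core-consensus decoys in the AT-rich interior, and the estimated
  profile is pulled towards the core consensus (total variation ~0.04
  at strength 0.97, ~0.19 at 0.9). Real weak-BP species are subject to
  the same bias; their BP profiles should be read as "profiles of what
  the scan accepts".
- The Frechet mixture's likelihood optimum is required to reach the
  planted parameters' likelihood, and all parameters except a
  scale-dominated long-component location are recovered to 10%. A
  Frechet's density vanishes exponentially towards its location, so a
  location buried under the other component (e.g. 60 nt under a
  short component peaking there) is unidentifiable at n = 20,000 —
  simulation shows ±30% errors with the fitted likelihood *exceeding*
  the planted one. The default long component sits at 2 kb, where its
  location is identified.
- 5-mer log-odds are recovered to 0.05 bits mean absolute error on a
  long-intron planting. On short introns the splicing signals
  themselves (the PPT especially) contribute genuine 5-mer bias, so
  whole-intron composition differs from the interior model by design,
  not by estimation error.

Passing these tests therefore shows that the pipeline's estimators are
correct and consistent under the generative model. It does not show
robustness to what the generator omits: alignment errors, alternative
splicing, transcript-coverage artefacts, heterogeneous (non-iid) genome
composition, splicing enhancers/silencers, or any correlation between
features — on real data those appear as part of the information
deficit.

## Degenerate inputs and numerical details

Empty intron sets, profiles with zero accepted branch points, all-equal
length vectors, fewer than two taxa, and fewer than three shared leaves
raise errors; sub-minimal strata, insufficient flanks and sub-100
BP-positive sets warn and are skipped or flagged. Ambiguous bases score
zero in motif windows and are rejected in Markov scoring. Problem sizes
throughout the test suite and the acceptance script (20,000 introns for
recovery, 1,200 per species across 8-species clades, 2,000 short introns
for decompositions) were chosen as the smallest sizes at which the
stated tolerances are comfortably stable.
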