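---
title: "Methods: rG4 detection, subtype rules, the mini language model and variant statistics"
author: "g4scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rG4 detection, subtype rules, the mini language model and variant statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scan)
```

## The problem

RNA G-quadruplexes (rG4s) are four-stranded structures formed by stacked
G-tetrads in guanine-rich RNA, enriched in mRNA untranslated regions where
they modulate translation, splicing and stability. A canonical rG4 is four
runs of at least three guanines separated by loops of 1–7 nt,
G≥3 (N1–7 G≥3)×3. Single-nucleotide variants that hit a G-run can abolish
the structure; such rG4-breaking variants are expected to be under negative
selection and enriched among pathogenic alleles. `g4scan` provides a
desk-scale toolkit for this analysis chain: exact rule-based subtype
classification, reference window scorers, a trainable miniature RNA
language model, variant delta-score scanning, gradient-based
interpretation, flank motif enrichment, and the population-genetic test
battery — all exercised end to end on synthetic data with known truth.

## Subtype rule engine

Sequences are assigned hierarchically to the most stable class whose
pattern they match:

| rank | class | definition (defaults) |
|---|---|---|
| 1 | CANONICAL | four maximal G-runs ≥ 3, loops 1–7 nt |
| 2 | LONGLOOP | as canonical, exactly one loop 8–12 nt |
| 3 | BULGES | one run carries a single 1-nt non-G bulge (G·x·GG etc., total G ≥ 3); others ≥ 3 |
| 4 | TWO_QUARTET | four G-runs ≥ 2, loops 1–9 nt |
| 5 | POTENTIAL_GQ_40 | four G-runs ≥ 2, loops 1–30 nt, G content ≥ 40% |
| 6 | POTENTIAL_G_TRIPLEX_40 | three G-runs ≥ 3, loops 1–7 nt, G ≥ 40% |
| 7 | G_RICH_40 | G content ≥ 40% only |
| 8 | UNKNOWN | none of the above |

Every bound is a knob in `pattern_config()`. Two rules deserve comment.
First, G-runs are always *maximal*: a run of four guanines is reported
whole, never split to manufacture an artificial loop; matching is
implemented over the list of maximal runs rather than with a bare regular
expression, which also lets loops contain isolated guanines shorter than
the run threshold. Second, the two "potential" classes are checked before
the bare G-content class: anything matching them also satisfies G ≥ 40%, so
the reverse order would make them unreachable. G content is computed over
the full input sequence, not the motif window — a documented choice where
the literature is silent. Ties between spans of the same class resolve to
the leftmost span.

## Reference scorers

`g4hunter_base_scores()` scores each base in a G-run of length ℓ as
min(ℓ, 4), C-runs negatively, A/U zero; window scores are arithmetic means
(default window 60 nt, the screener convention) and the sequence score is
the max over windows. `cgcc_score()` is the ratio-type G/C run-weight
scorer: maximal runs are weighted per base by run length (defaults 10/20/30
for runs of 1/2/≥3, configurable), and the window score is
(G-weight + 1)/(C-weight + 1); the pseudocount of 1 on both sides keeps the
neutral sequence at exactly 1 and prevents division by zero. Conventional
decision thresholds (4.5 for cGcC, 0.9 for G4Hunter, 0.5 for probabilistic
scorers) live in `scorer_thresholds()`. Every scorer — rule oracle,
baseline, or the fine-tuned model — implements one contract
(`new_scorer()`, `score_sequences()`), so the downstream stages are
scorer-agnostic. Raw-scale and probabilistic scorers are never
unit-converted into each other; threshold schemes are scheme-specific.

## The miniature language model

The model is a BERT-style bidirectional transformer over overlapping 6-mer
tokens (vocabulary 4^6 k-mers plus [PAD]/[UNK]/[CLS]/[SEP]/[MASK]).
Sequences tokenize to L−5 tokens; token lists longer than 510 are split
into consecutive non-overlapping chunks, while tokens inside a chunk still
overlap by five bases. Because no deep-learning framework is part of this
package's dependency set — and because the encoder is the core of the
method — the transformer is implemented directly in base-R matrix algebra:
token + learned positional embeddings, pre-LayerNorm blocks with
multi-head self-attention and a GELU feed-forward layer (the smooth
BERT-family nonlinearity, which also keeps attribution path integrals
second-order accurate), residual
connections, a final LayerNorm, a masked-token head and a mean-pooled
softmax classification head. The backward pass is analytic (verified
against finite differences in the test suite) and also yields gradients
with respect to the input token embeddings, which is what integrated
gradients integrates.

Desk-scale defaults in `model_config()` are 2 layers, 2 heads, hidden 64,
feed-forward 128, ≤ 94 content tokens; pre-training uses standard 15%
masking (80% [MASK] / 10% random / 10% unchanged — the masking fraction is
a knob) with Adam at 1e-3, and fine-tuning runs 2 epochs (binary) or 5
(multiclass) at batch 32. The full-scale published configuration (6 layers,
6 heads, lr 4e-4, effective batch 250, 200k steps; fine-tune lr 2e-4) is
expressible through the same fields but is never required by the tests:
the point of the miniature model is to exercise the mechanism — dataset
recipe, masking, fine-tuning, attribution — not to reproduce trained
weights. Mean pooling (rather than the [CLS] vector) feeds the classifier
because it converges much faster at this scale; at convergence the two are
equivalent in capacity for these sequence lengths.

Dataset construction follows the published recipe: positives are
deduplicated by exact sequence and extended with transcript flanks to at
most 70 nt; negatives are matches of the relaxed putative-G4 pattern
G≥2 (N1–30 G≥2)×3 in rG4-free background transcripts, centered in windows
whose lengths are drawn from the empirical positive-length distribution
(the matching algorithm is not specified in the literature; sampling the
empirical distribution is this package's choice), with at most 1200
negatives per 10-nt match-length bin between 10 and 60 nt. Cross-validation
is stratified (also a documented local choice — it stabilizes per-fold
metrics at small n); multiclass AUCs are macro one-vs-rest averages.

## Variant effects

`delta_score()` computes Δ = mutant − wild-type probability on
identically-placed windows containing the variant; the default window
policy centers a 70-nt window on the variant and clips at transcript ends
(the scanning geometry is unstated in the source literature; variant-
centered windows make wild-type and mutant scores exactly comparable). Two
published threshold schemes coexist and are never merged: the gnomAD-style
scheme (BREAKING iff wt > 0.7 and mut < 0.3; NON_BREAKING iff wt > 0.7 and
|Δ| ≤ 0.02) and the biobank-style scheme (BREAKING iff wt > 0.5 and
Δ ≤ −0.2; FORMING iff wt < 0.5 and Δ ≥ +0.2). Records matching neither band
are kept as OTHER rather than dropped, for auditability. When a variant
maps to several transcripts, `reduce_min_delta()` keeps the most disruptive
instance, breaking ties lexicographically. `estimate_fdr()` scores sliding
windows (70 nt, stride 10) over transcripts assumed rG4-free and reports
the fraction exceeding 0.7 — windows, not transcripts, form the
denominator.

## Interpretation

Integrated gradients runs along straight lines in token-embedding space
from each of three reference baselines to the input, with 200 midpoint
Riemann steps; attribution per token is the path-averaged gradient times
the embedding displacement, summed over embedding dimensions (the
alternative — max over dimensions — is not used; summation preserves the
completeness axiom) and averaged over baselines. Baselines are the three
non-rG4 sequences whose mean final hidden states lie nearest the
coordinate-wise median representation of the baseline class; length
mismatches are resolved by trimming or repeat-cropping the baseline token
sequence. Completeness (attributions summing to the output difference)
holds exactly for linear models and to well under 1% on the compact
mini-LM at 200 steps; both are asserted in the tests. One caveat is worth
stating: the finite-step error of the path integral scales with the
sharpness of the classifier's transition along the path, so a very
strongly trained model can need more than 200 uniform steps to reach 1% —
the error still decreases toward zero with the step count. The
completeness checks therefore use a compact fine-tuned model (120 + 120
examples), which is the documented condition for that property. Tokens overlapping the motif are
zeroed, significance against a reference set of non-motif token
attributions uses two-sided t-tests with Benjamini-Hochberg control at
q < 0.05, and nucleotide/2-mer/3-mer projections take the maximum over
covering significant 6-mers within ±20 nt of the motif. The flank
perturbation scan substitutes each G→C and C→G one at a time within ≤60-nt
flanks of high-confidence motifs and aggregates mean Δ by substitution type
and relative position.

Two conditions matter when reading perturbation maps on synthetic data.
First, the synthetic label is a pure function of the motif, so flanks carry
no label signal by construction; the directional asymmetry (G→C more
destabilizing than C→G) emerges through the guanine-density proxy the model
learns when negatives are motif-free, and can invert when the negatives are
themselves G-rich. Second, a classifier saturated near probability 1
responds to single-base flank changes only at noise level (~1e-5); the
perturbation tests therefore use a moderately trained model with mid-range
scores. Real transcriptome models escape both caveats because real flanks
do carry signal.

## Motif enrichment

Flanks of canonical motifs in sequences scored > 0.7 (forming) and < 0.3
(non-forming) — the band between is excluded — are scanned with position
probability matrices by log-odds against a uniform background (pseudocount
1e-3). Instead of an external scanner, the null distribution of the window
score is computed *exactly* by discretising per-column scores to a 1e-3
grid and convolving column by column; a sequence has a hit when any offset
reaches the score whose null tail probability is below 1e-4. A consequence
of the exact null: motifs shorter than 7 columns cannot reach p < 1e-4
(4^-6 > 1e-4) and simply produce no hits — tests and examples use ≥ 7-nt
PWMs. Enrichment per motif is
log2((fraction of forming sequences with a hit + ε)/(fraction of
non-forming with a hit + ε)) with ε = 1e-6, a one-sided Fisher exact test
on the 2×2 unique-sequence table, BH across motifs, and the report filter
(total hits ≥ 5, q < 0.05, log2 fold change > 1). Both flanks of one motif
count as a single flanking-sequence unit. The uniform background (rather
than a 0-order model fit to the input) is a documented choice.

## Selection statistics

The battery mirrors the population-genetic analyses: a call-rate filter
(AN ≥ 80% of 152,312 by default), constraint-quartile matching
(group A's empirical quartiles define bins, ties to the lower bin; group B
is sampled without replacement to reproduce A's occupancy exactly, with
largest-remainder rounding when sizes differ), one-tailed KS or
Mann-Whitney comparisons of allele frequencies under the alternative
"breaking MAFs stochastically smaller", the rare-variant fraction
(strict MAF < 0.1%), length stratification (short ≤ 22 nt, long ≥ 28 or
≥ 31 nt; the middle band excluded), equal-width CADD-bin trends of Δ,
2×K chi-square subtype-distribution shifts, Welch's ANOVA with Games-Howell
post hocs (or Kruskal-Wallis with Dunn + BH — the two are never mixed in
one call), and the ClinVar-style pathogenicity contrast. Games-Howell and
Dunn are implemented from their standard formulas (Tukey-studentized range
with Welch degrees of freedom; rank sums with tie correction) because no
installed package provides them; all simpler tests call the base-R
implementations. Fold enrichment for pathogenicity — not spelled out
formulaically in the source literature — is defined here as the pathogenic
fraction among structure-abolishing variants (Δ ≤ −0.5) divided by the
pathogenic fraction among all scored rG4-region variants, with a binomial
tail test of the abolishing subset at the baseline rate; the baseline set
is configurable.

## Synthetic data: what it emulates and what it does not

`simulate_transcriptome()` draws i.i.d. backgrounds at a requested GC
content (a first-order option exists for harder language-model tasks) and
plants one motif per transcript from the requested subtype mix, generated
from each class's grammar, with non-G buffer bases at the boundaries; a
plant whose local window fails to classify as intended is re-rolled, so
planted truth is exact by construction. Motif-free backgrounds are scrubbed
of relaxed putative-G4 matches by switching one G of a GG dinucleotide to
C per match — this preserves GC content exactly while guaranteeing a clean
negative background. `simulate_variants()` targets G-runs of planted motifs
for breaking variants (requiring that the substitution actually destroys a
canonical plant) and flanks for neutral ones; MAFs come from Beta(0.3, 30)
for breaking versus Beta(0.5, 30) for neutral under the selection regime —
means of 1% versus 1.6%, a realistic scale for UTR variants — and from the
neutral Beta for both under the null; AN, constraint Z and CADD are drawn
with configurable shifts. `plant_pwm_sites()` writes per-column-sampled
PWM sites into flanks at given per-sequence rates.

What passing tests therefore show: the machinery — rules, recipe, model,
attribution, statistics — behaves exactly as specified on data whose truth
is known. What they do not show: performance on real transcriptomes, where
rG4 signal is confounded by composition, transcript structure, experimental
noise and subtype imbalance; none of the published benchmark numbers on
external datasets are reproduced or claimed here.

## Numerical choices and problem sizes

Window scores use exact cumulative sums; softmax rows are max-shifted;
LayerNorm uses ε = 1e-5; Adam uses the standard bias correction; MLM
evaluation masks a held-out slice under a fixed seed so identical seeds
give identical losses. The test suite and the acceptance script run the
learnability check with 4000 examples (3200 train / 800 held out), 60
pre-training steps on 400 windows and 2 fine-tuning epochs — sizes chosen
so the whole suite completes on a single CPU in minutes while leaving the
headline margins (held-out ROC-AUC ≥ 0.95, breaking-variant negative-delta
fraction ≥ 0.9) wide. The calibration check uses 200 null replicates of
120 + 120 variants; the planted-PWM recovery check uses 200 + 200 flanks at
planting rates 0.4 versus 0.05 over 50 replicates.

## Known limitations

The rule engine implements one defensible reading of the classical subtype
scheme; published pipelines differ in unstated details (G-content window,
bulge multiplicity, loop bounds for the relaxed classes), so every bound is
exposed in `PatternConfig` rather than hard-coded. The mini-LM is a
mechanism-scale model: its weights, capacity and training corpus are far
below the published full-scale system, and nothing here should be read as a
reimplementation of its accuracy. Multi-nucleotide and phased variants are
out of scope, as is genome-to-transcript liftover (variants arrive in
transcript coordinates), read-level rG4-seq signal emulation, and
population structure in the simulated allele frequencies.
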