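---
title: "A unified sequence model of transcription initiation and termination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A unified sequence model of transcription initiation and termination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

txunify asks how much of a compact eukaryotic genome's transcript structure
— where transcription starts, where the transcript is cleaved and
polyadenylated, and which strand is transcribed — can be read directly from
DNA sequence. It implements a two-layer model in the style used for budding
yeast: local sequence-feature classifiers that score every base for
promoter and cleavage/polyadenylation (CPA) potential on both strands, and
an eight-state strand-symmetric hidden Markov model (HMM) that integrates
the four resulting score tracks into genome-wide transcript structure.

```{r, eval = FALSE}
library(txunify)
train <- generate_random_genome(synthetic_genome_spec(n_genes = 200, seed = 1))
model <- train_unified_model(train$genome, train$annotations)
test  <- generate_random_genome(synthetic_genome_spec(n_genes = 100, seed = 2))
decoded <- decode_genome(test$genome, model)
transcript_match(decoded$transcripts, test$annotations, end_offset_bp = 200)
```

## The classifiers

Two Random-Forest classifiers score sequence windows anchored at a
candidate base:

* **Initiation.** A 600-bp window from −500 to +100 relative to the
  candidate TSS, cut into six bins at −300, −150, −80, −50 and 0. The
  −150:−80 bin hosts the general regulatory factor (GRF) sites (Reb1,
  Abf1, Rap1, plus Rsc3), −80:−50 the TATA box, and 0:+100 the first
  transcribed bases. Per bin the features are the maximum log-odds score
  of each motif, G/C fraction, and the longest poly(dA)/poly(dT) run; the
  A:T ratio is measured only in the 0:+100 bin, where coding-strand A
  enrichment makes it informative and directional.
* **Termination.** Three 50-bp bins spanning −75 to +75 around the
  candidate CPA site, with the Hrp1 efficiency-element score (optimal site
  TATATA), G/C fraction and poly(dA)/poly(dT) runs per bin. These two
  feature families — base content and Hrp1 sites — carry essentially all
  of the termination signal.

Minus-strand anchors are featurized on the reverse complement, so offsets
always read 5′→3′ along the putative transcript and extraction is exactly
strand-symmetric (a tested invariant).

Training follows a leave-one-chromosome-out design: for each held-out
chromosome, replicate forests are trained on the remainder (the canonical
configuration is 8 folds × 4 replicates × 50 trees = 1600 trees);
prediction averages all forests' class probabilities. Class imbalance
(tens of negatives per positive) is handled by a balanced bootstrap per
tree, which affects calibration but not ranking. Negative examples tile
the non-promoter genome in overlapping 600-bp windows (stride 300) and
transcript bodies in overlapping 150-bp segments (stride 75). One design
point matters more than it looks: the exclusion zone around annotated
TSSs applies to the *same strand only*, so anchors that read the reverse
strand of a real promoter are kept as negatives. Those are the examples
that teach the classifier orientation — the TATA box, the CA initiator
and the A:T ratio are the only strand-asymmetric parts of an otherwise
bidirectional promoter signal (GRF sites and poly(dA:dT) act through
nucleosome depletion, which has no orientation) — and without them the
downstream HMM happily fills intergenic gaps with mirror-image antisense
transcripts.

`reduce_features()` implements importance-ordered greedy selection:
features are ranked by impurity importance, added one at a time, and
retained only if they improve AUROC on held-aside refinement data by at
least 0.002 (configurable; "appreciable improvement" is not a sharply
defined quantity). `train_logistic()` offers a ridge-penalized linear
alternative with the same scoring contract.

## The eight-state unified model

The HMM's states are intergenic (IG), TSS+, Gene+, CPA+ and their
minus-strand mirrors, plus a single bidirectional terminator state (Term)
shared by convergent gene pairs. Its observations are the four classifier
tracks (initiation and termination on each strand), emitted as diagonal
Gaussians — means and variances per state and track, with no covariance
terms, since nothing in the model's formulation calls for them. Of the
64 conceivable transitions, 24 are allowed: eight self-loops, the two
strand cycles IG→TSS+→Gene+→CPA+→IG and IG→CPA−→Gene−→TSS−→IG,
Gene+→Term→Gene−, and six shortcuts for divergent (TSS−→TSS+), tandem
(CPA+→TSS+, TSS−→CPA−) and convergent (CPA+→CPA−, CPA+→Term, Term→CPA−)
gene adjacencies. The shortcut set is a reconstruction from genomic
logic: it is σ-closed and leaves exactly 40 transitions at zero.

### Strand symmetry

Chromosome strand labels are arbitrary, so decoding must be invariant
under reverse complement. Write σ for the involution that swaps + and −
states (fixing IG and Term) and swaps the strand tracks. Emissions are
tied as mean[s,o] = mean[σs,σo] (likewise variances). For transitions the
naive tie A[a,b] = A[σb,σa] looks natural but is wrong: it forces A to be
doubly stochastic, whose stationary distribution is uniform — all eight
states would be occupied equally and every estimated dwell time collapses.
The condition that actually makes every state path exactly as probable as
its reverse-complement image is the *flow* tie

> π(a)·A[a,b] = π(σb)·A[σb,σa],  with π stationary and π(σs) = π(s),

under which path probabilities telescope. `symmetrize()` therefore
averages the flow matrix π·A with its σ-mirror and Sinkhorn-balances it
back to equal row and column marginals; at convergence the balanced flows
are unique, so the tie and stationarity hold to machine precision, the
initial distribution is the (σ-symmetric) stationary distribution, and
the operation is idempotent. Counting parameters the conventional way —
nonzero transitions individually, emission means and variances once per
σ-orbit — gives 24 + 16 + 16 = 56 free nonzero parameters.

### Parameter estimation

`estimate_parameters()` takes a per-base 8-state transcript map and the
observation tracks and computes per-state emission moments and normalized
adjacent-base transition counts (restricted to the allowed set), then
symmetrizes. The default is the plain empirical moments. The pipeline
wrapper `train_unified_model()` enables two refinements whose necessity
is easy to underestimate:

* **Robust moments** (median/MAD). Classifier score peaks are wider than
  the annotated TSS/CPA states, so score bleed contaminates the tails of
  the IG and Gene score distributions. With raw moments the IG means for
  the termination tracks come out several-fold too high, and genuinely
  quiet intergenic DNA then fits the *Gene* states better than IG — the
  decoder paints intergenic regions as transcript. Medians and MADs keep
  the contamination out.
* **Pooled-variance flooring.** With per-state variances, whichever
  quiet state happens to have the narrowest spread wins quiet regions on
  Gaussian normalization alone, independent of its mean; with variances
  pooled *down*, the genuinely broad CPA/TSS score profiles (a peak rising
  from 0.05 to 1.0 across a state) become impossibly expensive at their
  shoulders. Flooring each state's variance at the occupancy-weighted
  pooled value equalizes the quiet states while letting peak states keep
  their wide spreads.

The training state map widens the TSS/CPA states to the classifiers'
effective resolution (70 bp and 150 bp by default) rather than the narrow
annotation defaults (26/36 bp, the documented spread of start and cleavage
positions), again so that peak shoulders fall into the states built to
emit them.

`tune_means()` optionally re-tunes the 16 tied means by Nelder–Mead
(at most 500 evaluations) to maximize the Pearson correlation between the
posterior probability of being a transcript — defined as 1 − P(IG), the
simplest reading, with strand-resolved variants available — and a per-base
log expression track.

### Decoding and transcript calling

`posterior_decode()` runs scaled forward–backward (C++ via Rcpp; per-base
rescaling makes underflow impossible) and returns per-base posterior
marginals over the eight states, which sum to one at every base and agree
with brute-force path enumeration to well below 1e−8 on small chains.

`predict_transcripts()` turns posteriors into transcript calls. A naive
rule — maximal runs of strand-transcript posterior above a threshold —
is fragile for two structural reasons observed on simulated data: support
dips briefly inside long bodies wherever the local score context happens
to look intergenic (the body itself carries little per-base signal), and
the bidirectional terminator complex is absorbed by either strand's CPA
state arbitrarily, truncating runs at the 3′ end. The caller therefore
parses the posterior's anchor states directly: scanning each strand in
transcription order, a TSS-state posterior peak opens a transcript and
the farthest terminator-complex peak (CPA+ + CPA− + Term, strand-agnostic
because cleavage signals act bidirectionally) still supported by the
strand posterior closes it. Support means the rolling 700-bp mean of the
strand-transcript posterior stays at or above the threshold (default
0.45) across the span, so sub-window dips pass and intergenic stretches
fail; among supported terminator candidates the one with the greatest
local terminator posterior mass wins, since a genuine terminator sustains
near-1 posterior over hundreds of bases while a mid-body blip does not.
This realizes the same contract as the run rule — raising the threshold
still yields a subset of called bases — but is robust to the two failure
modes. Called ends can optionally be refined against the raw classifier
tracks (`refine_transcript_anchors()`), whose peaks are sharply centred on
the sites they were trained at; exact-base calls use the initiator (CA,
more generally YR) and cleavage ([G/C]AA) micro-motifs via `locate_tss()`
and `locate_cpa()`.

## The synthetic-data generator

`generate_random_genome()` emulates everything the pipeline needs without
external data: i.i.d. background at 38% G/C (A = T = 0.31), genes of
500–1500 bp separated by 0.8–1.4 kb gaps (about one gene per 2 kb), with
an implanted promoter grammar (one sampled GRF site in −150:−80, a
10–20 bp poly(dA:dT) tract, a TATA box in −80:−50 in half of promoters,
and a CA initiator at the TSS) and terminator grammar (2–4 TATATA sites
within 60 bp upstream of the CPA inside an AT-rich 150-bp window, with a
[G/C]AA cleavage site). About a third of gene units are convergent pairs
whose CPA regions overlap in a shared bidirectional terminator — without
them the Term state is never observed and cannot be estimated. Transcribed
bodies carry an A-over-T excess on the coding strand (0.16, rising to
0.24 in the first 100 bases; G/C content is untouched), reflecting the
A-richness of transcribed yeast sequence and giving the A:T-ratio feature
something to measure. The companion simulators produce per-base expression
tracks (log-normal transcript abundances, multiplicative noise),
combinatorial promoter-library designs with disrupted-site controls,
sort-seq bin counts, and pseudo-random 3-kb fragments with inserted
consensus sites.

What the generator does *not* emulate is worth stating: nucleosome
positioning, codon structure and splicing, pervasive low-level antisense
and cryptic transcripts, distance-dependent enhancer effects, and
experimental noise in expression measurements. Passing the end-to-end
suite therefore demonstrates that the pipeline's machinery is correct and
self-consistent under the stated grammar — not that it attains any
particular accuracy on real genomes, where the printed benchmarks of the
field depend on curated annotations and expression data.

The bundled motif matrices are small illustrative PFMs shaped after the
factors' published consensi (file
`inst/extdata/pfm/core_motifs_synthetic.pfm`, flagged synthetic by name);
curated matrices can be supplied via `read_pfm()`/`read_meme()`.

## Numerical and design choices

* Coordinates are 0-based half-open internally; BED is read/written
  natively, GFF3 converted at the boundary.
* Bases covered by annotated transcripts on both strands (other than
  overlapping CPA regions, which become Term) are masked out of parameter
  estimation — the model has no states for simultaneous sense/antisense
  transcription — but keep the label IG for decoding comparisons.
* Motif bin scores take the maximum (not mean) log-odds of matches
  starting in the bin; maxima are monotone under bin extension, which the
  suite checks.
* Genome scoring uses a 10-bp anchor stride by default (well under the
  classifiers' intrinsic resolution), carrying the last score forward and
  masking window-infeasible edge bases to the track minimum.
* Peak calling merges score runs closer than 150 bp (the termination
  window width) and breaks summit ties leftmost; fine-mapping breaks
  motif-distance ties 5′-most.
* The transcript-level evaluator matches greedily by summed end distance
  with a 200-bp end tolerance; the test suite checks it against exhaustive
  assignment for small inputs. Per-base precision applies its positional
  tolerance to precision only (with an option for both).
* Reported problem sizes: the end-to-end suite trains on a 200-gene
  (~600 kb, 8-chromosome) genome and decodes an independent 100-gene
  genome; parameter recovery uses 1 Mb simulated directly from known
  parameters; posterior-versus-enumeration checks use chains of length
  up to 12 for 2–3 states and length 5 for the full 8-state model.

## Known limitations

Emission independence across the four tracks is a modelling convenience;
initiation and termination scores are correlated at bidirectional
elements. The anchor-scan caller assumes each transcript ends at a
terminator-complex peak, so a transcript whose terminator the classifier
misses entirely is not called (the HMM posterior alone cannot conjure the
missing evidence). Overlapping sense/antisense transcription is outside
the state space by construction. Expression-level prediction is a
non-goal: the model predicts transcript structure, not abundance.
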