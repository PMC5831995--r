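---
title: "plantlincs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantlincs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`plantlincs`, the assumptions behind them, the tunable parameters, the
synthetic-data generators used to test them, and the numerical and design
choices made where more than one reasonable option existed.

## The prediction problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt with
poor protein-coding capacity. Long *intergenic* ncRNAs (lincRNAs) are the
subclass whose genomic loci fall between protein-coding genes,
overlapping no gene body. Predicting them from an assembled plant
transcriptome combines three kinds of evidence:

* **intrinsic coding potential** — the length of the longest open reading
  frame and the fraction of the transcript it covers, plus short
  nucleotide-composition patterns that differ between coding and
  non-coding sequence;
* **genomic context** — where the transcript maps relative to annotated
  genes;
* **homology** — similarity to known proteins (a reason to reject) and to
  known lncRNAs (a reason to accept).

The package's final call requires agreement between a trained classifier
and lncRNA-database annotation, after location and length filters. This
conjunction is deliberately conservative: the SVM alone is permissive and
annotation alone depends entirely on database coverage; their
intersection inherits the specificity of both.

## Features

For a transcript $t$ of length $L$:

* `orf_length` — nucleotide length (stop codon included) of the longest
  span ATG … first in-frame stop (TAA/TAG/TGA), scanned in the three
  forward frames only. Transcripts are assumed to be oriented (assembled
  cDNA), so the reverse strand is not scanned. An ATG running off the end
  of the sequence without a stop is *not* an ORF by default
  (`allowOpenEnded = FALSE`); this strict definition avoids rewarding
  truncated assemblies with inflated ORFs. Ties between equal-length ORFs
  break to the smallest start, then the smallest frame, making the result
  deterministic. The residue count `aa_length = orf_length/3 − 1` is
  carried alongside because the field's operational lincRNA landmark is a
  longest ORF under 100 amino acids.
* `orf_proportion` — `orf_length / L`, in $[0,1]$; equals 1 exactly when
  the ORF spans the whole transcript.
* pattern frequencies — for each selected pattern $p$ of width
  $k \in \{2,3,4\}$, the fraction of valid overlapping $k$-windows equal
  to $p$. Windows containing a non-ACGT character are excluded from both
  numerator and denominator, so N-rich assemblies do not systematically
  deflate frequencies; a sequence with no valid window scores 0
  everywhere. Frequencies are normalized per width, never pooled across
  widths — this keeps a trimer column (e.g. CCC in the maize preset) on
  the same scale as the dimer columns, with mean $4^{-k}$ within its own
  width.

Codons containing ambiguous bases match neither ATG nor a stop; they are
simply ordinary non-matching codons during the ORF scan.

## Pattern selection

All 336 possible 2-/3-/4-mers are candidate features. Selection is:
z-score each of the 336 pooled frequency columns (zero-variance columns
are dropped and score 0), run PCA, pick the component whose sample scores
have the largest absolute point-biserial correlation with the class
label, orient it so the positive class has positive mean score, score
every feature by |loading| on that component, and keep the top
`nSelect = 10`.

Two decisions here were genuinely open and are pinned as follows:

* *Which component?* The single most class-correlated one. This is the
  simplest deterministic reading of "PCA identifies the discriminative
  patterns"; the choice is isolated in one place so a multi-component
  scheme could be swapped in.
* *Standardize first?* Yes, by z-score: dimer frequencies live near 1/16
  and tetramers near 1/256, so unstandardized PCA would order features by
  raw variance and never select a tetramer.

When the two classes are statistically identical every component's
correlation is ~0; the function warns ("no discriminative component") and
falls back to PC1's loadings rather than failing.

The two published per-organism pattern lists are shipped as presets so
prediction can bypass selection exactly as the original per-organism
models did. That the two presets differ (all dimers for sugarcane; CA
replaced by AC plus the trimer CCC for maize) is the reason trained
models embed their own pattern list: a model archive must be sufficient
to reproduce its feature extraction.

## The classifier

An RBF-kernel SVM, for three reasons: the decision boundary need not be
linear in the 12 features; the method is non-parametric in the sample
size; and the tuned parameters are exactly (C, γ), matching standard
libSVM practice. Training:

1. classes balanced to equal size by seeded down-sampling of the larger
   (unbalanced training would bias the margin);
2. stratified, seeded 80/20 train/test split (`testFraction = 0.2`,
   configurable — published splits vary);
3. features z-scored with training-split statistics only; the stored
   (mean, sd) pairs are reused verbatim at prediction time. Constant
   features are flagged and passed through unscaled rather than dividing
   by zero;
4. grid search over C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,−13,…,3} (the libSVM
   practical-guide ranges) by mean 10-fold cross-validated accuracy on
   the training split, with stratified seeded folds; ties break to the
   smallest C, then smallest γ (prefer the smoother model);
5. refit on the full training split; accuracy reported once on the
   hold-out.

Model selection uses CV accuracy because accuracy is the metric the
workflow reports; sensitivity and specificity are available through
`evaluateModel()`. Transcripts shorter than 4 nt cannot support feature
extraction and predict as the sentinel label `"too_short"`; downstream
code treats them as negative.

A note on the *no-signal null*: handing the trainer two literally
identical feature matrices does not produce chance-level hold-out
accuracy — each held-out vector is usually present verbatim among the
other class's training rows, so the SVM predicts the opposite label and
accuracy lands systematically *below* 0.5 (about 0.37 in our
measurements). The meaningful null — features carrying no class
information — is two independent draws from the same distribution, and
that is what the tests use; it sits at 0.500 ± binomial noise.

## The cascade

Stages, in the default (generic/sugarcane) layout:

| stage | rule | default |
|---|---|---|
| `coding_filter` | remove transcripts with ≥ 1 protein-database hit at e-value ≤ threshold | 10⁻¹⁰ |
| `length_filter` | keep length ≥ `minLength` (inclusive) | 200 nt |
| `intergenic_filter` | keep mapped transcripts none of whose alignments overlaps any gene body by ≥ 1 bp (strand-agnostic) | distance ≥ 0 |
| `svm_predict` / `lnc_annotate` | parallel: SVM label; any lncRNA-database hit at e-value ≤ threshold | 10⁻¹² |
| `intersection` | final calls = SVM-positive ∩ annotated | — |

The e-value thresholds are exposed in `pipelineConfig()` rather than
hard-coded; no published values exist for the two filters, so the coding
threshold defaults to a conservative 10⁻¹⁰ and the annotation threshold
to 10⁻¹², matching the similarity threshold the differential-expression
procedure does publish. All e-value comparisons in the package are
inclusive (≤), and the 200 bp boundary keeps length exactly 200.

"Intergenic" is pinned to *zero overlap with any gene body*: an
alignment merely touching a gene boundary shares no base and survives;
a single overlapping alignment disqualifies a multi-mapping transcript
(the safest reading); unmapped transcripts are dropped because their
location cannot be verified. A stricter notion of intergenic is available
via `minGeneDistance` (bp to the nearest gene, default 0).

The `maize` layout enters at the length filter (read mapping and
consensus assembly have already produced its input) and applies the
coding filter second. The coding and length filters commute — the tests
assert this — so the layouts differ in the stage ordering of the report,
not in the final set.

Interval containers are `GRanges` (1-based, closed), the Bioconductor
convention, with conversions confined to the parse boundary: GFF3
(1-based closed) imports unchanged, BED (0-based half-open) is shifted on
import by `rtracklayer`. The half-open "touching means no overlap"
semantics of BED inputs are preserved exactly: BED `[200,300)` against a
gene ending at base 200 shares zero bases and is intergenic.

Stage collapse (zero survivors) completes the run with an empty final set
and a warning, never an error: an empty result is a legitimate finding.

## Presence/absence differential expression

Predicted lincRNAs from all libraries are pooled with library-qualified
row ids (`library:transcript`); near-identical sequences from two
libraries are deliberately distinct rows, matching how per-library
predictions are produced. Cell $(r, L)$ of the matrix is YES iff $L$ is
$r$'s home library or $r$ has a similarity hit (query = $r$, subject in
$L$) with e-value ≤ 10⁻¹² (inclusive). Self-presence is forced true
whether or not self-hits appear in the hit table; presence follows the
query→subject direction because each library's sequences are queried
against the pooled database.

A row is differentially expressed iff it has at least one YES among
treated libraries and all NO among controls, or vice-versa. Because every
row is YES in its home library, the rule reduces to "absent from the
entire other condition", is symmetric under swapping the condition
labels, and with an empty hit table every row is differential (the
maximal-count bound — the tests assert it).

`naiveSimilarityHits()` is a deliberately naive exact-substring matcher
(quadratic, fixed e-value 10⁻³⁰) that stands in for an external
similarity search in fixtures and tests only; it is not a BLAST
replacement.

## Synthetic data: what it emulates, and what it does not

`simulateLabeledTranscripts()` has two modes.

**`classMode = "orf"`** (default) emulates the *coding-structure*
difference the classifier exploits. Negatives (PCT-like) carry a sense
codon ORF of ≥ 100 residues (uniform over the 61 non-stop codons) flanked
by uniform UTR-like sequence, with total length capped so the ORF covers
≥ 60% of the transcript. Positives (lincRNA-like) are uniform iid
background with planted pattern insertions, post-edited by replacing a
mid-ORF codon with a random stop until the longest ORF is ≤ 99 residues.
The 100-amino-acid class boundary is asserted on every generated batch.
`enforceLincCeiling = FALSE` relaxes the positive ceiling, emulating the
looser lncRNA positive sets used when no lincRNA-labeled training data
exist.

**`classMode = "composition"`** makes both classes the same uniform
background and differs *only* in the planted insertions. This is the mode
in which planted-pattern recovery is well-posed: codon-structured
negatives carry real composition signal of their own (depletion of
stop-codon patterns inside ORFs, start-codon enrichment; standardized
shifts up to ≈ 0.55), which a correct selector will legitimately rank
alongside planted patterns. Recovery tests must not punish the selector
for finding true signal, so they isolate the planted truth.

Patterns are planted by seeded motif insertion: a multiplier $m$ for a
width-$k$ pattern overwrites ≈ $(m−1)\,W\,4^{-k}$ random windows (W =
number of windows) with the motif, raising its expected frequency by the
factor $m$. The default planted set is ten tetramers (AATT, ATAA, CACT,
CGTG, CTGC, GAGG, CGCC, GTCC, TAGA, TTCA; multiplier 3.5), chosen by
combinatorial search so that their twenty sub-trimers are pairwise
distinct, all sixteen dimers appear 1–2 times among their sub-dimers, and
motif letters and boundary letters are balanced. Under these constraints
each sub- or super-pattern of a motif receives at most about half the
planted pattern's standardized shift, and — because the pooled motif
content is compositionally background-like — no unplanted pattern is
systematically crowded out of the background. Two alternatives were
evaluated and rejected:

* *Markov transition reweighting for dimers*: boosting a→b chains with
  other boosted transitions and shifts the stationary distribution,
  producing unplanted higher-order patterns with standardized shifts
  comparable to the planted ones;
* *planting short motifs by insertion*: shifting a dimer's frequency
  requires overwriting so much sequence that background occurrences of
  every *other* pattern are depleted, making unplanted dimers spuriously
  discriminative (short patterns are hit hardest because their
  standardized sensitivity to a uniform depletion scales with
  $\sqrt{4^{-k}}$).

Multiplier 3.5 puts the planted standardized shift well above both the
sub-pattern leakage (≈ half) and, in composition mode, the zero intrinsic
background; it also separates the class-correlated principal component's
eigenvalue from the bulk, which stabilizes the loading ranking across
seeds (at weaker planting the component rotates noticeably between
seeds).

What the generators do **not** emulate: real codon-usage bias (codons are
uniform), splice structure, expression-level variation, assembly
artifacts, sequencing error, paralogy, or genuine lncRNA sequence
families. Passing tests therefore demonstrate that the implementation is
correct on data satisfying its assumptions — not that the published
accuracies transfer to any particular real transcriptome, which depends
on training data quality and database coverage.

`simulateToyGenome()` places non-overlapping genes on one chromosome with
gaps of 3 transcript-lengths, then places each transcript either
overlapping a gene (by ≥ 1 bp) or strictly inside a gap, with the truth
manifest recording each placement. `simulateCascadeFixture()` builds a
transcript set whose stage counts are known by construction; the SVM
stage counts are forced by drawing clean survivors from a labeled
generator pool and keeping only candidates the supplied model labels as
intended (with an error if the model and generator agree too rarely), so
fixtures remain valid for any adequately trained model.

## Numerical choices and degenerate inputs

* All e-value and length comparisons are inclusive.
* FASTA ids are the header token before the first whitespace; duplicates
  and empty sequences are hard errors, not warnings.
* BLAST tabular rows with fewer than 12 columns, or with unparseable
  numeric fields, raise errors naming the line; extra columns are
  ignored. E-value 0.0 (maximal significance) is legal.
* BED rows need ≥ 4 columns (the name column carries the transcript id)
  and `start < end`; GFF3 records with `end < start` are rejected by the
  importer. When a GFF3 file carries a biotype attribute and any gene is
  `protein_coding`, only protein-coding genes enter the annotation.
* Model archives are versioned; loading a mismatched version, a truncated
  file or an archive missing its scaling parameters is an error, never a
  silent default model.
* Hits and alignments referencing unknown ids warn once at pipeline entry
  and are ignored thereafter.
* Grid-search ties prefer smaller C then smaller γ; equal-length ORFs
  prefer the leftmost start then the lowest frame; pattern-score ties
  keep candidate order (dimers before trimers before tetramers).
* Everything stochastic (generators, balancing, splits, folds) is a pure
  function of an integer seed; re-running with the same seed reproduces
  byte-identical FASTA fixtures and model archives.

## Problem sizes used by the test suite

The test suite and `scripts/acceptance.R` validate: the ORF finder
against a brute-force enumerator on 1000 random sequences (lengths
1–600, with ambiguous bases); per-width frequency normalization on 1000
sequences; planted-pattern recovery at 1000 + 1000 composition-mode
transcripts (≥ 8 of 10 required); classifier hold-out accuracy ≥ 0.95 at
2000 + 2000 ORF-mode transcripts with the full default grid; the
no-signal null at 200 + 200 feature rows over 10 seeds (reduced grid —
the null property does not depend on the grid); 50 randomized cascade
fixtures plus one forced-count fixture; the differential-expression rule
against brute-force evaluation on 1000 random presence matrices; and
byte-level determinism of fixtures, models and reports. Smaller unit
tests pin every boundary (199/200 nt, e-value exactly 10⁻¹²,
zero-overlap adjacency).

## Known limitations

* ORFs are scanned on the given strand only; antisense ORFs in
  mis-oriented assemblies are invisible.
* The intergenic filter trusts the supplied alignments; it cannot detect
  transcripts that failed to map for technical reasons (they are dropped,
  which may discard true lincRNAs in poorly assembled genomes).
* The selection criterion uses a single principal component; class
  signal spread across several components is only partially captured.
* Presence/absence differential expression ignores coverage: a sequence
  weakly present in both conditions is called non-differential no matter
  how different its abundance. Coverage-based calls are out of scope.
* The conjunction with database annotation bounds recall by database
  coverage — transcripts without a similar known lncRNA can never reach
  the final set, however convincing their other evidence.
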