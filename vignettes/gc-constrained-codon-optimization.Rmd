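---
title: "GC-constrained codon optimization: model, objective, and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC-constrained codon optimization: model, objective, and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Synonymous codon choice has large effects on heterologous protein expression
in *Escherichia coli*: codon adaptation (CAI, tAI) correlates with expression
level, while composition properties — GC content near 52%, weak mRNA
structure around the start codon, absence of inhibitory motifs such as
internal Shine–Dalgarno sites and poly-U tracts — affect transcript
stability and translation initiation. Optimizers that simply maximize codon
adaptation tend to drift in GC content and to concentrate probability on a
few high-frequency codons.

`codonopt` treats codon optimization as *constrained conditional modeling*:
a backend model predicts, for every masked residue of a protein, a
distribution over that residue's synonymous codons; training minimizes a
masked-language-modeling (MLM) loss subject to a GC-content constraint
enforced by an augmented-Lagrangian method; decoding turns the trained
distributions into sequences, optionally under hard GC bounds via a
constrained beam search. Every piece is exercisable at desk scale against a
synthetic corpus generator, so the full pipeline — curate, train, optimize,
evaluate — runs in minutes on one CPU with no external data.

## Token scheme

The vocabulary couples amino-acid identity and codon identity in single
tokens (`m_atg`, `k_aaa`, `stop_taa`, ...): 64 codon-bearing tokens (61
sense + 3 stops, the stops grouped as one synonymous family under a
dedicated stop symbol), 20 masked amino-acid tokens (`a_unk` ... `y_unk`)
representing residues whose codon is not yet chosen, and 5 special tokens
(`unk`, `cls`, `sep`, `pad`, `mask`) — 89 tokens in total. (Published
descriptions of this token scheme state a total of 90 while enumerating the
same categories; the enumeration is what is operational, so this package
follows it and records the scalar as a discrepancy.) Each token carries a GC
fraction — the number of G/C letters among the codon's three nucleotides
divided by 3, zero for non-codon tokens — which is the lookup table behind
the differentiable GC estimate. A protein `MALW` is represented as
`m_unk a_unk l_unk w_unk`; prediction replaces each masked token with a
member of its synonymous family, which is why decoded sequences translate
back to the input protein *by construction* rather than by filtering.

## The training objective

With $L_{MLM}$ the masked-language-modeling loss

$$L_{MLM} = -\frac{1}{|M|}\sum_{i \in M} \log p_\theta(x_i^* \mid x_{-i}),$$

the total loss is the augmented-Lagrangian form

$$L_{total} = L_{MLM} + \lambda\,(GC - \mu) + \frac{\rho}{2}\,(GC - \mu)^2,$$

where $\mu = 0.52$ is the GC target for *E. coli*, $\lambda$ the dual
variable and $\rho$ an adaptive penalty coefficient. $GC$ is a
differentiable estimate of the GC content of the model's predictions (see
below). Constraint terms are disabled during a 3-epoch curriculum warm-up so
the model first fits host codon usage; afterwards $\lambda$ and $\rho$
undergo scheduled updates every 20 optimization steps:

* deviation $\Delta_k = GC_{sm} - \mu$, violation $v_k = |\Delta_k|$, with
  $GC_{sm}$ an exponential moving average (coefficient $\alpha = 0.1$) of
  the per-batch estimate;
* dual update $\lambda_{k+1} = \lambda_k + \rho_k \Delta_k$ — the multiplier
  rises when GC runs above target, pushing probability toward low-GC codons,
  and falls when below;
* penalty update
  $\rho_{k+1} = \min(\max(\rho_{min}, \rho_k\,p_{inc}), \rho_{max})$
  applied only when the violation persists ($v_k > \epsilon$) *and* the
  relative improvement since the previous scheduled update,
  $r_k = (v_{k-1} - v_k)/\max(v_{k-1}, 10^{-8})$, is inadequate
  ($r_k < \eta$); otherwise $\rho$ is unchanged.

$r_k$ has no canonical published definition; the relative decrease of the
violation between scheduled updates is the simplest quantity matching the
intended semantics ("tighten only when progress is inadequate") and is what
`penalty_update()` implements, with a small denominator floor. Defaults
where no published value exists are conservative augmented-Lagrangian
practice, all configurable and logged: $\lambda_0 = 0$, $\rho_0 = 1$,
$\epsilon = 0.005$, $\eta = 0.05$, $p_{inc} = 2$,
$\rho \in [0.1, 100]$. Probabilities are floored at $10^{-12}$ inside
logarithms.

### Which GC estimate? (a design decision)

The GC term needs a differentiable estimate of the GC content of *the
sequences the model will emit*. Three estimators are implemented
(`constraint_config(gc_estimator = ...)`):

* `"expectation"` — the probability-weighted mean
  $\frac{1}{|M|}\sum_i \sum_c p_i(c)\, gc(c)$. This controls the mean of
  the predicted distributions, but when the conditional distributions are
  genuinely high-entropy (as they are for any corpus whose codon choice is
  stochastic given context) the constraint can be satisfied by *flattening*
  distributions while every argmax stays a high-GC codon: the expectation
  reaches $\mu$ while greedily decoded sequences remain far above it. We
  measured exactly this failure on the synthetic corpus (decoded GC ≈ 0.63
  with the soft estimate at ≈ 0.51).
* `"sharpened"` — the expectation under temperature-sharpened
  distributions ($z/\tau$, default $\tau = 0.25$). Closer to the decoded
  GC, but once training makes the model confident the sharpened softmax
  saturates and the constraint gradient vanishes.
* `"straight_through"` (default) — the batch GC is evaluated on the argmax
  codons (the value that greedy decoding will realize) while the gradient
  is taken through the soft expectation. This is the standard
  straight-through construction for constraining statistics of discrete
  outputs: the dual variable integrates the *actual* decoded-GC violation,
  so the scheduled updates drive the decoded GC itself to $\mu$, and the
  gradient path never saturates.

With the default estimator, training on a synthetic corpus generated at
GC ≈ 0.62 brings the mean greedily-decoded GC of held-out proteins to
$0.52 \pm 0.01$ across seeds while validation MLM loss stays below the
untrained baseline — the package's acceptance surface, recomputed by
`scripts/acceptance.R` and the test suite.

## The reference backend

The trainable backend is deliberately compact: per synonymous family, base
logits per codon plus (with `context_width = 1`, the default) additive
features of the left and right neighboring residues. It honors the masking
contract of a much larger masked language model — probability mass outside
the masked residue's family is exactly zero — so the rest of the pipeline
(objective, decoding, evaluation) is agnostic to whether predictions come
from this model or from an external network plugged in behind the same
interface. Training is plain minibatch gradient descent with analytic
softmax gradients (verified against finite differences in the tests) and a
cosine-annealing-with-warm-restarts schedule.

`training_config()` defaults mirror a transformer-scale recipe (15 epochs,
batch size 6, learning rate $5\times10^{-5}$) for provenance; for this
logit-table backend the package's own experiments use `learning_rate = 1`,
which the acceptance script passes explicitly. All positions are masked per
sequence by default (`mask_ratio = 1`), matching the inference task, where
every codon must be predicted; the published masking ratio for fine-tuning
is unstated, so the ratio is exposed as configuration.

## Decoding

* **Greedy**: argmax within each residue's family; exact ties resolve to
  the lexicographically first codon.
* **Sampling**: per-position sampling with logits divided by a temperature;
  the $T \to 0$ limit reproduces greedy.
* **Constrained beam search** (`beam_size = 5`, `length_penalty = 1.0`
  defaults; 10 / 1.2 documented alternatives): each partial sequence tracks
  its cumulative GC nucleotide count; expansions whose *achievable final GC
  interval* (cumulative count plus the sum of per-remaining-residue family
  minimum/maximum GC counts) cannot intersect the bounds are pruned. The
  interval is exact, so pruning is sound — it never removes a feasible
  completion; this soundness is itself tested by equivalence against an
  exhaustive constrained argmax on small proteins. Candidates with equal GC
  count are merged keeping the better prefix (their suffix problems are
  identical), which makes the search exact whenever the beam is at least as
  wide as the number of live GC classes. If no synonymous assignment can
  satisfy the bounds (poly-Phe against a 50% floor, for example), an
  explicit infeasibility report is returned; an out-of-bounds sequence is
  never emitted silently.

GC bounds default to 50–56%, are *inclusive* (the lower bound equals the GC
of forced sequences such as `ATGTGG`, which exclusive bounds would
spuriously reject), and apply to the whole emitted sequence. For DNA inputs
the start codon is preserved verbatim at position 1 — start-codon identity
affects initiation, not synonymy — and the stop codon is re-chosen among
TAA/TAG/TGA by backend score; protein inputs decode all residues (plus an
appended stop by default).

Numerical determinism: log-probability comparisons in beam search and in
the exhaustive oracle are quantized at $10^{-9}$ before ordering, so
mathematically equal scores accumulated in different orders compare as
ties and resolve lexicographically — both search routes return bit-identical
sequences.

## Evaluation metrics

* **CAI**: geometric mean of relative-adaptiveness weights
  $w_c = f_c / \max_{c' \in fam} f_{c'}$ derived from a reference set of
  highly expressed genes (pseudocount 0.5 on zero counts). Following the
  standard Sharp–Li convention, ATG, TGG and stops are excluded from the
  geometric mean; this convention is not universal, so the exclusion list
  is an argument. The reference set itself is an input — there is no
  canonical published table bundled as a constant.
* **tAI**: geometric mean of per-codon tRNA-adaptation weights over sense
  codons. Weights are an input table; `tai_weights_from_trna()` derives a
  dos-Reis-style table from tRNA gene copy numbers with the standard wobble
  constraints (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68).
* **GC content**: literal (G+C)/length.
* **5′ MFE**: folding score of the first 50 nt. The bundled default backend
  is Nussinov base-pair maximization (Watson–Crick + G:U pairs, minimum
  hairpin loop 3, −1 per pair) — a *structural proxy in arbitrary units*,
  not a thermodynamic energy; the `"vienna"` backend calls the external
  `RNAfold` for kcal/mol values. Δ5′MFE values are only meaningful within a
  single backend. The per-gene Δ5′MFE is reported per sequence and both
  aggregate readings (mean of per-gene differences; difference of per-method
  MFE means) are recoverable from the report, since the published choice
  between them is unstated (on fully matched gene sets they coincide).
* **Inhibitory cis elements**: counts of catalogue motifs — default
  catalogue: internal Shine–Dalgarno consensus `AGGAGG` (counted with
  overlaps, restricted to positions after codon 1) and poly-U tracts (a run
  of ≥ 5 T's, counted once per maximal run). The catalogue behind published
  counts is unstated, so it is a swappable TSV
  (`inst/extdata/cis_catalogue_default.tsv`); counts are reported raw per
  gene (no per-kb normalization, which is likewise unstated).
* **Benchmark report**: per-method means ± SD, success rates (protein
  preserved and GC within bounds), and paired two-sided *t*-tests of each
  method against the originals over matched gene ids, Bonferroni-corrected
  across method comparisons per metric. Methods covering only a subset of
  genes are compared at their reduced matched *n*. Degenerate cases are
  reported honestly: identical pairs give $t = 0, p = 1$; a zero-variance
  nonzero shift is "undefined (zero variance)"; fewer than 2 pairs omits
  the test with a reason.

## The synthetic corpus generator

The generator emulates the *structure* of a curated high-expression gene
corpus without any external data: per-family codon-usage distributions with
controllable sharpness (`bias_strength`, log-normal family weights) and a
log-linear GC tilt (`gc_shift`, per G/C nucleotide); start/stop codons at
approximate natural *E. coli* frequencies (ATG 83%, GTG 14%, TTG 2.7%,
CTG 0.3%; TAA 63%, TGA 29%, TAG 8%); amino-acid composition uniform by
default so codon-level effects stay isolated; lengths from a shifted
geometric distribution with mean 150 codons (typical of bacterial genes,
and fast at desk scale), truncated to [30, 500]. `find_gc_shift()` solves
the closed-form expected-GC equation for the tilt that reaches a requested
corpus GC, which is how the study corpus at GC ≈ 0.62 is produced.

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: codon choice is i.i.d. given the amino
acid (no codon-pair bias, no autocorrelation, no position-dependent usage),
there is no genomic context (operons, UTRs, regulatory overlap), no
sequencing noise, and the high/low-expression split is a clean two-table
mixture rather than a continuum. Results on this corpus validate the
*machinery* — constraint control, search soundness, metric arithmetic — not
biological effect sizes.

## Problem sizes and study conditions

The test suite and `scripts/acceptance.R` use, as the package's standard
desk-scale conditions: 500 random proteins of 10–300 residues for the
beam-search safety sweep; a 200-gene corpus at GC ≈ 0.62 (85/15
train/validation split), 15 training epochs, batch 6, learning rate 1,
default constraint configuration, and 100 held-out proteins of 50–200
residues per seed across 3 seeds for GC-target recovery; 100 proteins of
≤ 8 residues with a beam at least as wide as the enumeration for oracle
equivalence; and sequences of ≤ 16 nt for exhaustive folding enumeration.

## Known limitations

* The backend is a local-context model; it cannot represent the long-range
  dependencies a sparse-attention transformer captures. The contract lets a
  pretrained network be plugged in, but none is bundled.
* The Nussinov fallback ranks structures by pair count only; use the
  ViennaRNA backend for thermodynamic statements.
* Beam search constrains whole-sequence GC only; motif avoidance and
  windowed-structure constraints inside the beam are out of scope.
* CAI/tAI depend entirely on the supplied reference/weight tables; the
  package ships no claimed *E. coli* tables.
* The augmented-Lagrangian scheduler is control machinery, not a
  convergence theorem: pathological learning-rate/penalty combinations can
  oscillate. The history log (λ, ρ, GC, violation per step) is the intended
  diagnostic.
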