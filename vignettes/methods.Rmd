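---
title: "Methods: HLA imputation with an emulated encrypted inference path"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA imputation with an emulated encrypted inference path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The statistical model

HLA imputation exploits the strong linkage disequilibrium between an HLA
allele and its flanking SNP haplotype. `hlaimpute` treats each two-field
allele of a gene as its own binary classification problem: for allele
$k$ of a gene with $K$ alleles, a logistic regression

$$\Pr(\text{allele } k \text{ present} \mid x) =
  \sigma(w_k^\top x + b_k), \qquad \sigma(s) = \frac{1}{1+e^{-s}},$$

is fitted on the reference panel, with $x \in \{0,1,2\}^M$ the SNP
dosages of a sample and the response the *binary* presence of the allele
(a homozygote is labelled 1, not 2). The $K$ fitted rows form the weight
matrix $W$ used at inference time.

Inference for one sample and one gene proceeds in four stages:

1. **Linear**: scores $y = Wx + b$, one per allele.
2. **Top-2**: the indices $a_f, a_s$ of the two largest scores. Ties
   break toward the lower allele index; because the sigmoid is strictly
   increasing, selecting on raw scores or on probabilities is
   equivalent, and the package selects on raw scores and applies the
   sigmoid only to the two survivors.
3. **Sigmoid**: $p_f = \sigma(y_{a_f})$, $p_s = \sigma(y_{a_s})$, putting
   the two candidates on a common probability scale.
4. **Threshold**: the call is homozygous $(a_f, a_f)$ iff
   $p_f \ge p_s \cdot t$ (boundary included), else heterozygous
   $(a_f, a_s)$. The first reported allele always equals the top-scoring
   one.

The integer threshold $t$ controls how much better the best candidate
must be before the second candidate is discarded. It is selected on a
validation split by grid search over $t \in \{2, \dots, 20\}$,
maximizing mean pair accuracy; ties break toward the smallest $t$, the
value most willing to call heterozygotes, which is the safer default
since heterozygotes dominate at realistic allele-frequency spectra.

### Training choices

The fit maximizes the L2-penalized Bernoulli log-likelihood by a damped
Newton (IRLS) method with an unpenalized intercept. Defaults:
$\lambda = 10^{-4}$, gradient tolerance $10^{-8}$, at most 200
iterations. The penalty exists for numerical, not statistical, reasons:
with tag SNPs a rare allele is often perfectly separated, and an
unpenalized fit would diverge. $\lambda = 10^{-4}$ is small enough to
leave informative weights essentially unshrunk. The solver is
deterministic, so retraining on identical inputs reproduces the model
bit for bit; this matters because the encrypted path quantizes the
weights and any training nondeterminism would masquerade as quantization
error. Monomorphic SNPs are dropped before fitting (they carry no
information and corrupt the score-bound estimate described below);
alleles whose labels are constant in the training split are retained
with zero weights and intercept $-50$ — a score no fitted allele
produces — and flagged, so allele indices remain stable for downstream
consumers. The validation split is a seeded uniform draw of a
configurable fraction (default 20%) of reference samples; explicit
sample lists can be supplied instead when a study dictates the split.

## The emulated encrypted path

A TFHE-style server computes the same four stages over integers modulo a
ciphertext modulus $Q$. The package reproduces this arithmetic exactly,
minus keys and noise, so the encrypted pipeline's *numerical* behaviour
can be audited against the plaintext oracle. All torus values are stored
as doubles holding integers in $[0, Q)$; with the default $Q = 2^{32}$
every intermediate stays far inside the $2^{53}$ exact-integer range.

* **Fixed-point encoding.** Reals are multiplied by `scale` (default
  $2^{20}$) and rounded; negatives wrap modulo $Q$. Encoding then
  decoding is exact to within $1/(2\cdot\text{scale})$.
* **Linear.** Weights are encoded once; dosages are small integers, so
  each per-allele dot product is accumulated exactly, chunk by chunk
  with `pack_size` SNPs per chunk (default 2048, one packed ciphertext
  per chunk). Integer addition is associative, so the chunking provably
  never changes the result; the implementation checks that the
  accumulated score stays below $Q/2$ and errors rather than alias.
* **Normalization.** $\mathrm{normalize}(x) = 0$ for $x \le T$ and
  $\frac{Q}{4}\cdot\frac{x-T}{B-T}$ (rounded) for $T < x \le B$, mapping
  scores onto $[0, Q/4]$ as the comparison circuits require. $B$ is
  estimated during training as the maximum absolute linear score on the
  training panel times a 1.25 safety factor and stored in the model;
  $T = -B$ by default. Scores above $B$ clamp to $B$ with a logged
  count — a rare-tail policy preferred over a hard error because a
  clamped score is still the gene's runaway winner. A value landing
  exactly on $Q/4$ is pulled back one unit before selection, since the
  mux identity needs payloads strictly below $Q/4$.
* **Comparison circuits.** $\mathrm{cmpbit}(x)$ returns $Q/2$ iff the
  signed representative of $x$ is $\ge 0$ (so equality selects the left
  argument — the deterministic tie-break), and
  $\mathrm{mux}(x) = x - Q/2$ for $x \ge Q/2$, else $0$. Then
  $\max(a,b) = \mathrm{mux}(c + a) + \mathrm{mux}(Q/2 - c + b)$ with
  $c = \mathrm{cmpbit}(a-b)$, and $\min(a,b) = a + b - \max(a,b)$. Top-2
  is a sequential scan keeping a running (top, second) pair. Allele
  indices ride through the circuits as separate payloads selected by the
  *same* $c$-controlled identity — the natural lift that makes the
  circuits return indices rather than scores; the test suite verifies it
  exhaustively on a toy modulus. With the scan order and the
  left-wins-on-equality rule, ties resolve toward the earlier allele
  index, matching the plaintext tie-break exactly.
* **LUT sigmoid.** Programmable bootstrapping evaluates an arbitrary
  function as a table lookup indexed by the top bits of a ciphertext.
  The emulation uses a `lut_size`-entry table (default 2048) whose entry
  $i$ holds the encoded $\sigma(\mathrm{normalize}^{-1}(\cdot))$ at the
  centre of cell $i$. The absolute error against the exact composition
  is at most (max slope $\tfrac14$) × (cell width $(B-T)/\text{lut\_size}$
  in score units) + $1/(2\cdot\text{scale})$ — about $2.4\times10^{-3}$
  at $B = 10$ — and the tests audit this bound by sweep.
* **Threshold.** Comparing $p_f$ with $p_s \cdot t$ could overflow, so
  the circuit instead divides the encoded $p_f$ by $t$
  (round-to-nearest) and compares with $p_s$; the second index is again
  selected by the mux identity, and the first needs no circuit at all.

Disagreements between the two paths can therefore only arise within one
LUT cell of the $p_f$ vs $p_s\cdot t$ decision boundary, and shrink as
`scale` and `lut_size` grow; both properties are asserted by the test
suite on simulated cohorts. Parameter defaults
($Q = 2^{32}$, scale $2^{20}$, 2048-entry LUT) were chosen so the
quantization bound is far below typical decision margins; all are
configurable through `fp_params()`.

## The synthetic study design

`simulate_panels()` generates the study the tests run on. Each allele of
each gene owns a block of `tag_block_size` tag SNPs (default 4) set to 1
only on haplotypes carrying that allele; haplotypes flip each tag SNP
independently with probability `noise_rate` (default 0.01, roughly the
tagging imperfection of a dense MHC scaffold); allele frequencies are a
symmetric Dirichlet draw with concentration 0.35, which at realistic
panel sizes yields both rare (MAF < 0.01) and common alleles, mirroring
observed HLA spectra; `hom_enrichment` (default 0.1) makes a sample's
two haplotypes share their allele draws with that probability, planting
the homozygotes that threshold tuning needs. Defaults of 600 reference
and 200 target samples over two genes (6 and 10 alleles) keep a full
train–tune–impute–evaluate cycle in seconds. Reference panels emit
presence markers consistent with the drawn alleles, so the
diploid-presence QC (exactly two presence counts per gene per sample)
passes by construction; the same QC removes malformed samples from real
panels.

What the generator does *not* emulate: recombination and realistic MHC
LD decay (flips are i.i.d., so there is no haplotype mosaic structure),
population demography, phasing error, and genotyping platform artefacts.
Passing tests therefore demonstrate that the pipeline and its encrypted
emulation are *mutually consistent* and that the method recovers planted
structure; they do not certify accuracy on real panels, where LD is
weaker and reference and target populations can diverge. On noise-free
simulations with at least two tag SNPs per allele the pipeline attains
pair accuracy 1.0 on held-out samples whenever every target allele was
trainable — an allele absent from the reference panel can never be
imputed, the same limitation real reference panels have, and rare
alleles are where accuracy degrades first as noise rises.

## Numerical and degenerate-input policy

* Missing genotypes are rejected at load: the pipeline sits downstream
  of pre-imputation, so completeness is a contract, not a repair task.
* Multi-allelic / non-SNP VCF records are skipped with a count; marker
  alleles are matched as written, with no strand harmonization.
* Presence markers are decoded by character (P = carried, A = absent)
  regardless of the declared allele order in the markers file.
* `top2` requires at least two alleles; genes with fewer than two
  trainable alleles refuse to train.
* The threshold boundary uses $\ge$ (equality calls homozygous), the
  cmpbit boundary returns $Q/2$ at zero, and the mux joint maps $Q/2$
  to 0 — all exactly as their piecewise definitions state.
* Division by $t$ rounds to nearest; at default precision the induced
  error is below one encoding unit.

## Problem sizes used by the tests

The suite validates the circuits exhaustively at a toy modulus
($Q = 2^{10}$: all $1024$ residues for cmpbit, all $256^2$ pairs for
max/min), the top-2 circuit on 1000 random 99-allele score vectors
(the largest allele count among the classical genes), pipeline
concordance on a 200-sample, two-gene simulated cohort, and
accuracy/threshold behaviour on simulations of 150–500 reference
samples. These sizes were chosen as the smallest that exercise every
code path and tie-break; all scale linearly if larger studies are
wanted.

## Known limitations

* The emulation covers the integer semantics of the encrypted pipeline,
  not its cryptography: no keys, no LWE noise, no bootstrapping failure
  modes. A deployment must separately verify that its parameter set
  keeps cryptographic noise below one LUT cell.
* One model per allele ignores the sum-to-one structure across a gene's
  alleles; the top-2 + threshold stages compensate in practice, but
  probabilities are not calibrated jointly.
* P-group mapping and deprecated-allele lists are user-supplied tables;
  the package does not fetch nomenclature databases.
* Imputation quality scores (posterior dosage uncertainty) are not
  produced; the service model returns allele indices only, with
  probabilities available behind an explicit flag.
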