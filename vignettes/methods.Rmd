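---
title: "Methods: junction attention for circRNA prediction and zero-shot backsplice discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction attention for circRNA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(backsplicer)
```

## The problem and the model

Backsplicing ligates a splice donor to an *upstream* acceptor, producing a
circular RNA. Detection tools that align reads to backsplice junctions
cannot say anything about genes without dedicated RNA-seq; this package
instead learns to predict circRNA production from the junction sequence
context alone, at either of two levels:

* **isoform level** — given one isoform's exon set, is this isoform a
  circRNA?
* **gene level** — given all exon–intron boundaries of a gene, does any
  junction pair backsplice?

Both reduce to binary classification of a record `(S, E(S))` where `S` is
the transcribed-strand sequence and `E(S) = {(a_i, d_i)}` the ordered exon
junctions (1-based, inclusive; `a_i` the first exonic base, `d_i` the
last). The model never sees anything outside the flanking windows of those
junctions.

### Architecture

1. **Flanking windows.** Each junction contributes the positions
   `center - floor((L-1)/2) … center + floor(L/2)` (exactly `L` positions;
   with the default `L = 4`: one upstream, the center, two downstream).
   The bracketed index arithmetic is read as floor; this is the only
   reading that yields `L` positions for every `L`.
2. **k-mer embedding.** The k-mer centered on each window position (same
   floor convention) is encoded base-4 (`A=0, C=1, G=2, T=3`, most
   significant first) and looked up in a trainable table of size
   `4^K + 1`. Windows that run off the sequence end or contain `N` map to
   the single reserved pad index `4^K`, whose embedding is trainable but
   shared — one sentinel keeps the vocabulary small and gives boundary
   junctions a learnable "missing context" representation.
3. **Junction encoders.** A bidirectional GRU (standard cell: update gate,
   reset gate, candidate state, `h_0 = 0`, biases included) reads the `L`
   embeddings; forward and backward states are concatenated per position
   and pooled by k-mer attention: `t_j = tanh(F_t(h_j))`,
   `alpha = softmax_j(t_j · t_s)`, `w = sum_j alpha_j h_j`. Acceptor and
   donor sides use four disjoint GRUs and separate attention parameters.
   The attention vectors `t_s`, `c_s` are free learned vectors (not
   tanh-transformed; only the projected hidden states pass through tanh,
   exactly as the scoring formula is written).
4. **Cross-attention.** Single-head dot-product attention in both
   directions: `beta^a_{i,j} = softmax_j(w_i^a · w_j^d)` with
   `v_i^a = sum_j beta^a_{i,j} w_j^d`, and symmetrically `beta^d_{j,i}`
   normalized **over acceptors** with `v_j^d = sum_i beta^d_{j,i} w_i^a`.
   (The source formula's denominator letters slip between sides in two
   places; both are resolved by the convention that `i` always indexes
   acceptors and `j` donors, which is the only reading that normalizes
   each softmax over the set its numerator ranges over.) No multi-head
   attention is used.
5. **Site attention and head.** `c_i = tanh(F_c(v_i))`,
   `gamma = softmax_i(c_i · c_s)`, `r = sum_i gamma_i v_i` per side;
   `y_hat = sigmoid(F_p(ReLU(F_r([r^a; r^d]))))`. A binary call is
   `1(y_hat > 0.5)` (strict).
6. **Loss.** Standard (negative) binary cross-entropy plus
   `lambda * ||theta||^2` over all trainable parameters, minimized — the
   convention the named loss implies; without the minus sign the printed
   quantity would be unbounded below.

### Zero-shot backsplice discovery

After training on gene labels only, the donor site-attention weight is
interpreted as `P(d_j) = gamma_j^d` and the donor-side cross-attention row
as `P(a_i | d_j) = beta^d_{j,i}`; both are softmax-normalized, so

    P(d_j, a_i) = gamma_j^d * beta^d_{j,i}

is a proper joint distribution over all (donor, acceptor) ordinal pairs of
a gene (sums to 1 within 1e-6; asserted on random models and trained
models). `backsplice_scores()` computes it from a forward pass's attention
maps; `rank_pairs()` orders pairs descending with deterministic tie-breaks
(donor then acceptor ordinal ascending). The candidate space defaults to
all ordinal pairs; `upstream_only = TRUE` restricts to `a_i <= d_j`, the
biologically possible direction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 3 | k-mer length (vocabulary `4^K + 1`) |
| `l` | 128 | k-mer embedding dimension |
| `L` | 4 | flanking-window length in positions |
| `h` | 128 | GRU hidden size per direction (site embeddings are `2h`) |
| `a_dim` | 16 | size of all attention vectors |
| `f_dim` | 128 | pre-output dense layer width |
| `lambda_l2` | 1e-3 | L2 weight on all parameters |
| `learning_rate` | 1e-3 | AMSGrad step size (`beta1 = 0.9`, `beta2 = 0.999`) |
| `batch_size` | 64 | minibatch size |

The defaults are the published operating point; sweeps over
`L ∈ {1,2,4,8,16,32,64}` and `K ∈ {1..5}` are expressible through the JSON
config. "Trained until convergence" is operationalized as early stopping on
validation loss (`patience = 5` epochs by default, `max_epochs = 100`),
with a group-aware 10% of the training records carved out for validation —
the stopping data are never described in the source, so the choice is
explicit and configurable. Parameters at the best validation loss are
returned.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates i.i.d. background sequence at a stated GC
content, genes of 2–6 exons (exon lengths 30–120 nt, introns and terminal
flanks 20–80 nt), and plants, in positive genes only, an acceptor motif
(`TTTCAG`, branch-point/polypyrimidine-like) centered on `a_i` and a donor
motif (`GTAAGT`, U1-consensus-like) centered on `d_j` of one uniformly
chosen pair with `i <= j` (upstream-directed, as real backsplices are),
then mutates each motif base independently (default rate 0.1, substitution
to a uniformly chosen different base). Motifs are centered on the junction
so they fall inside the default `L = 4, K = 3` receptive field
(positions `a-2 … a+4`); users who shrink `L` or `K` should re-center
accordingly. Labels are assigned by seeded sampling before any sequence is
drawn, so positives and negatives are exchangeable in length and
composition (tested).

It does **not** emulate: splice-site consensus at *non*-backsplice
junctions (real genes have GT/AG at every intron boundary; our negatives
have none), flanking inverted repeats / Alu pairing, expression levels,
reads, or paralog families beyond an optional point-mutated duplication
flag. A green signal-recovery test therefore establishes that the
architecture can find and localize junction-proximal sequence signal — not
that it separates real circRNAs from lncRNAs, where the discriminative
signal is weaker and distributed.

## Numerical choices

* All softmaxes subtract the row maximum before exponentiation; log terms
  clamp scores to `[1e-7, 1 - 1e-7]`.
* Initialization: fan-based (Glorot) uniform for embeddings, dense and
  recurrent weights; zero biases; attention vectors uniform with the same
  fan rule. Seeded and restorable — the RNG state of the caller is never
  clobbered.
* Internal RNG streams are salted by purpose (`mix_seed`): the group
  shuffle given seed 42 must not replay the label-assignment permutation
  drawn under the same seed 42. (Found the hard way: the unsalted streams
  made an 80/20 holdout exactly the positive class.)
* Gradients are hand-derived reverse-mode; the only subtle term is that
  `H_{t-1}` reaches the candidate state only through the reset product
  `R_t * H_{t-1}`. Verified against central finite differences over every
  parameter tensor.
* Padding is exact, not approximate: padded sites are sliced out before
  cross-attention, so a prediction is bit-identical under arbitrary
  changes to padded ids (asserted with `expect_identical`).
* **Determinism.** OpenBLAS GEMM is not bit-stable across calls even
  single-threaded (alignment-dependent kernels), so `deterministic = TRUE`
  (and the CLI `--deterministic` flag) switches to R's internal matrix
  product: bit-identical reruns at ~1.5x cost. The package also pins BLAS
  threads to 1 at load; containerized CPU limits are otherwise
  oversubscribed by core autodetection.
* Checkpoints are a single JSON text file with 17-significant-digit
  numbers, which round-trips doubles exactly.

## Design choices that were genuinely open

* **Gene-level exon merging.** How multi-isoform genes' exon lists are
  merged (union of boundaries vs union of exons) is not specified upstream;
  the package accepts whatever exon list it is given and stays agnostic.
* **Boundary windows** are padded (sentinel k-mer), not clamped to the
  sequence edge; stated here because the alternative changes features of
  terminal junctions.
* **Discovery evaluation** pools candidate pairs across genes (per-record
  averaging is available via `pooled = FALSE`); per-record top-1 accuracy
  is reported alongside for interpretability.
* **Dropout** is not applied (unstated in the source); bias terms are
  included in all dense layers.

## Known limitations

* Donor localization is a lottery. The donor-side site attention
  `gamma^d` operates on cross-attentive embeddings `v_j^d` that are
  mixtures of *acceptor* embeddings, so the classification objective
  exerts only indirect pressure to concentrate `gamma^d` on the true
  donor. Across training seeds the joint score's pooled discovery AUC is
  stable (≈ 0.91–0.95 on the default simulation), but per-record top-1
  accuracy varies widely (≈ 0.09–0.80 over seeds 1–3): the acceptor factor
  `beta^d_{j*,i}` localizes the acceptor almost always (≈ 0.9), while
  `gamma^d` sometimes converges to a diffuse optimum that classification
  cannot distinguish from a sharp one. This is a property of the
  architecture, not of the implementation.
* Training is CPU-bound R; the default desk-scale budget (2,000 genes,
  reduced model) trains in ~2–3 minutes per seed. The full published
  operating point on tens of thousands of genes is out of scope here.
* The BED12 reader materializes one record per line; gene-level merging,
  GTF parsing and liftover are out of scope.
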