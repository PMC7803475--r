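---
title: "Multi-level representation fusion for clinical semantic textual similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level representation fusion for clinical semantic textual similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsfuse)
```

## The task and the model

Clinical semantic textual similarity (STS) asks how close in meaning two
clinical text snippets are, on a continuous 0--5 scale: 0 means the
snippets are completely dissimilar, 5 that they are semantically
equivalent. Down-weighting near-duplicate content in electronic health
records — much of it produced by copy-and-paste and templating — is the
motivating application.

`stsfuse` models a snippet pair $(a, b)$ with three representations that
see the pair at different granularities, concatenated and regressed to a
score:

* **Sentence level.** The pair is jointly encoded by a transformer pair
  encoder in the standard two-segment format
  (`[CLS] a [SEP] b [SEP]`); the hidden state at the start marker is the
  pair vector $S$.
* **Character level.** A shared CNN (kernel size 3) runs over the
  characters of every token; token vectors are max-pooled over *all*
  tokens of both snippets into $C$. Character features are robust to the
  out-of-vocabulary tokens (dosages, abbreviations, misspellings)
  pervasive in clinical text.
* **Entity level**, two variants:
  * *Entity I* — each snippet is mapped to its per-token entity-type
    label sequence over the nine standard clinical mention types plus
    `"O"`; the two label sequences pass through a siamese convolutional
    encoder (shared embedding and convolution, kernel 3, 50 filters) and
    the pooled branch vectors $u_a$, $u_b$ are compared as
    $[\,u_a - u_b\,;\, u_a \odot u_b\,]$.
  * *Entity II* — entities mentioned in each snippet are looked up in a
    knowledge graph whose embeddings were trained with TransE; per
    snippet, entity vectors are average-pooled into $e_a$, $e_b$ and
    aggregated as $E = \tanh(W_e [\,e_a - e_b\,;\, e_a \odot e_b\,] + b_e)$.

The fused vector $f = [S; C; E]$ (in that fixed order; disabled
components are skipped) feeds a small MLP that outputs the predicted
score. Training minimises mean squared error against the gold score;
evaluation is by Pearson correlation (PCC) on predictions clipped to
$[0, 5]$.

## Preprocessing

Corpus preprocessing is deliberately minimal and *closed*: snippets are
lowercased and split on whitespace and on the symbols `[`, `]`, `/`,
`,`, `.`, each emitted as a standalone token, with one exception — a
period immediately flanked by digits on both sides is a decimal point
and stays inside its token (`"2.5 mg."` → `"2.5"`, `"mg"`, `"."`).
Fixing the symbol set exactly (rather than an open-ended "symbols like
these") is what makes tokenization reproducible; hyphens and other
punctuation pass through as ordinary characters. The transformer
encoder does **not** consume these tokens: it applies its own subword
tokenization to the raw lowercased text, as pretrained encoders do.

## The entity layer

Entity recognition is a *contract*: the model consumes only per-token
label sequences aligned 1:1 with the tokens, so any clinical NER system
can stand behind it. The bundled implementation is a dictionary tagger:
greedy longest-match, leftmost-first, over token n-grams against a
lexicon mapping surface strings to one of the nine mention types and,
optionally, to a knowledge-graph identifier. A *mention* is a maximal
run of identical non-`"O"` labels; this run-length convention is a
design choice (multi-token dictionary surfaces produce runs naturally,
and adjacent same-type mentions merge). Mention-level KG coverage — the
fraction of mentions carrying a KG identifier — is reported by
`kg_coverage()`, since in practice only a minority (roughly a fifth) of
recognised clinical mentions map into a medical knowledge graph by
dictionary lookup, and the entity-II branch must behave well under such
sparsity: snippets with no mapped entity pool to the zero vector.

## The entity-I convolution block

The siamese block embeds the 10 labels (dimension 50), applies one wide
convolution (zero padding of kernel−1 on each side, 50 filters, kernel
3) and average-pools to one vector per sequence. Two numerical choices
matter:

* The convolution is **linear before pooling**; the average is taken
  over the *input* length and only then passed through a bias and tanh.
  Because wide convolution places every input position under every
  kernel slot exactly once, this makes the pooled vector of a constant
  label sequence independent of its length — an interpretability
  property the tests assert (an all-`"O"` snippet looks the same whether
  it has 5 or 19 tokens). The price is that position information within
  the label sequence is not used by this block; a per-window
  nonlinearity would use it but would make pooled output drift with
  sequence length through the padded edge windows.
* Both branches share all parameters, so identical label sequences give
  identical branch vectors exactly, and swapping the inputs negates the
  difference half and preserves the product half of the output.

The comparison $[\,u_a - u_b\,;\, u_a \odot u_b\,]$ mirrors the
aggregation used for entity II, keeping the two entity variants
commensurable; the reference formulation leaves this combination
unspecified.

## Knowledge-graph embeddings

TransE embeds entities and relations in $\mathbb{R}^d$ ($d = 100$ by
default) so that $h + r \approx t$ for a true triple $(h, r, t)$,
trained by SGD on the margin ranking loss with squared-L2 dissimilarity,
uniform corruption of head or tail, and projection of entity vectors to
the unit sphere after every epoch. Two refinements proved necessary at
desk scale:

* **Filtered negatives.** A sampled corruption that is itself a true
  training triple is rejected (up to 25 redraws). On graphs with a
  handful of entities, unfiltered sampling turns a material fraction of
  updates into anti-signal and total separation of true triples from
  corruptions becomes unreachable.
* **Margin scale.** The default margin 1.0 suits realistic graphs; on a
  2--3 entity chain the unit-norm geometry leaves no room for a margin
  that large, and tests of such chains use margin 0.5.

KG embeddings are trained once and **frozen** during STS training; only
the aggregation parameters $W_e, b_e$ are trained with the model. This
matches the intended deployment, where the KG (and its embedding) is an
external resource.

## Encoder contract and the tiny encoder

A production configuration would load a pretrained uncased checkpoint
(general-domain or clinical); no such weights ship with the package.
`make_tiny_encoder()` supplies the contract's desk-scale implementation:
a 2-layer, 2-head transformer (hidden size 16 by default) with a
vocabulary harvested from the training corpus — whole words plus a full
single-character back-off, so any input encodes without failure. All
weights are seeded Gaussians; forward and backward passes are
implemented in plain R and verified against central finite differences
in the test suite. Pairs longer than the position budget (380 by
default) are truncated longest-segment-first. The encoder is fine-tuned
jointly with all other components.

## Training

All enabled components are optimised jointly with Adam for exactly the
configured number of epochs; the last epoch's parameters are the final
model (no best-epoch selection, matching the reference protocol). The
default configuration carries the reference hyperparameters: learning
rate $2 \times 10^{-5}$, 12 epochs, batch size 20, sequence length 380.
The $2 \times 10^{-5}$ rate is a *fine-tuning* rate, meaningful for a
pretrained encoder; experiments that train the tiny encoder from random
initialisation use 0.01, the conventional Adam rate for small models
trained from scratch. One master seed derives every stream (shuffling,
initialisation, negative sampling), so runs are bit-reproducible; an
early lesson encoded in the code is that vocabulary orderings must use
byte-wise (radix) sorting, never locale collation, or "determinism"
silently depends on `LC_COLLATE`.

## The synthetic generator

No gold clinical STS corpus is distributable, so the generator
constructs one whose similarity structure is known. Snippet pairs come
from five clinical-style template families (medication sig lines, exam
findings, diagnosis statements, care-plan instructions, symptom
reviews), each with two paraphrase variants whose entity-bearing words
are identical. The target score selects an edit regime keyed to the 0--5
annotation rubric:

| score | construction |
|-------|--------------|
| 5 | same template and fills, alternative paraphrase wording |
| 4 | same template and fills, one numeric detail (dose/count/frequency) changed |
| 3 | same template, one key entity slot replaced |
| 2 | same template frame, every slot refilled |
| 1 | different templates from the same topic class |
| 0 | templates from unrelated topic classes |

Every snippet additionally receives independent meaning-neutral
boilerplate (chart phrases such as "per report", "at this visit") with
probability 0.5 on each side. This emulates the hedging and template
variation of real notes and is what makes the construction a fair test
of *entity*-driven similarity: surface statistics are noisy while the
entity slots remain structured. Scores are the discrete levels
themselves, so the score histogram of a generated corpus reproduces the
requested mixture directly.

KG identifiers are assigned at the *mention occurrence* level: after
the corpus is generated, entries are selected (in seeded random order)
so that the realised fraction of mention occurrences carrying an
identifier matches the requested coverage as closely as the lexicon
granularity allows. Entry-level assignment cannot hit a mention-level
target because entry usage is heavily non-uniform across templates. The
toy KG is a randomised spanning chain plus random extra edges over the
mapped entities, with a small typed relation vocabulary; it guarantees
closure (every identifier resolves in the lexicon) and connectivity.

What the generator does *not* emulate: real EHR vocabulary breadth,
negation and assertion status, misspellings, and annotator noise in
gold scores. Tests passing on synthetic data therefore demonstrate that
the architecture can recover a constructed entity-driven signal — not
clinical-grade performance, which requires the gated challenge corpus
and pretrained encoder weights.

## Experiment sizes and expectations

The shipped experiments are sized for a single CPU:

* *Overfit sanity*: 16 generated pairs, full model, 200 epochs — the
  model must reach training PCC ≥ 0.95, demonstrating end-to-end
  gradient flow.
* *Ablation*: 650 generated pairs (500 train / 150 test) with full KG
  coverage, tiny encoder, Adam 0.01, 20 epochs per configuration, one
  shared seed across the seven component configurations (each entity
  variant and both, with and without the character module, entity-free,
  and sentence-only). Twenty epochs brings the loss near plateau; at
  half that, configurations are visibly under-trained and row order is
  unstable at the token-relabeling level. Under this construction every
  entity-enabled configuration evaluates at or above the entity-free
  one; the "entity I without characters" versus "entity-free" comparison
  is a near-tie, which mirrors how close those two settings score in the
  reference results on real data.
* *TransE sanity*: a 10-entity drug–treats–disease matching graph, the
  translation-friendly structure, must reach total separation of true
  triples from corruptions; entity norms are unit after every epoch.

## Known limitations

* The entity-I block is position-free (see above); type *order* within
  a snippet never influences $E_I$.
* The dictionary tagger has no notion of negation or assertion status;
  a negated and an affirmed mention of the same entity look identical
  to both entity branches — a known error mode of this model family.
* `aggregate_entities()` output is bounded in $(-1, 1)$ analytically;
  in floating point, saturated coordinates equal ±1 exactly.
* Cross-validation folds on very small corpora can have constant gold
  scores; such folds report `NA` with a warning rather than aborting.
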