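# stsfuse

Multi-level representation fusion for clinical semantic textual
similarity (STS) in R.

Clinical STS scores how close in meaning two clinical text snippets are
on a continuous 0–5 scale (0 = completely dissimilar, 5 = semantically
equivalent). It is the natural formulation for detecting copy-and-paste
and template redundancy in electronic health records, and it feeds
downstream applications such as clinical question answering and trial
matching. `stsfuse` is for NLP researchers and clinical-informatics
engineers who want a fully self-contained, dependency-light
implementation of a fused STS regressor — including its training loop,
evaluation harness, ablation machinery and a synthetic data generator —
that runs on a single CPU with no external weights, corpora or services.

## The model

A snippet pair (a, b) is encoded at three levels and the
representations are fused:

* **S** — sentence-level: a transformer pair encoder consumes
  `[CLS] a [SEP] b [SEP]`; S is the hidden state at the start marker.
  The encoder is a pluggable contract; the bundled `make_tiny_encoder()`
  is a seeded 2-layer, 2-head transformer for desk-scale work
  (production use would load a pretrained uncased checkpoint).
* **C** — character-level: a shared character CNN (kernel 3) encodes
  every token; token vectors are max-pooled over all tokens of both
  snippets. Robust to out-of-vocabulary dosages and abbreviations.
* **E** — entity-level, two variants:
  * *entity I*: per-token entity-type label sequences (nine clinical
    mention types + `O`, from a pluggable tagger; a dictionary tagger is
    bundled) through a siamese convolutional encoder, branches compared
    as `[u_a − u_b ; u_a ⊙ u_b]`;
  * *entity II*: knowledge-graph embeddings of the mentioned entities
    (TransE, d = 100), average-pooled per snippet and aggregated as
    `E = tanh(W_e [e_a − e_b ; e_a ⊙ e_b] + b_e)`.

The fused vector `f = [S; C; E]` feeds an MLP that predicts the score
`p = MLP(W f + b)`; training minimises mean squared error and the
evaluation metric is the Pearson correlation coefficient (PCC) on
predictions clipped to [0, 5]. Every gradient — including the
transformer's — is implemented in the package and verified against
finite differences in the test suite.

## Worked example

Entity analysis of a medication sig line with a three-entry lexicon:

```r
library(stsfuse)
lex <- entity_lexicon(c("zocor", "tablet", "mouth"),
                      c("MedicationMention", "MedicationMention",
                        "AnatomicalSiteMention"))
toks <- preprocess("Zocor 40 mg tablet 1 tablet by mouth one time daily.")
entity_mentions(tag_entities(toks, lex), toks)
#>   start end                  type surface
#> 1     1   1     MedicationMention   zocor
#> 2     4   4     MedicationMention  tablet
#> 3     6   6     MedicationMention  tablet
#> 4     8   8 AnatomicalSiteMention   mouth
```

Three medication mentions and one anatomical-site mention: the tagger
reproduces the canonical entity analysis of this sentence, and the label
sequence (`MedicationMention O O MedicationMention O MedicationMention
O AnatomicalSiteMention O O O O`) is what the entity-I branch consumes.

End-to-end on a synthetic corpus (≈2 minutes on one CPU):

```r
bundle <- generate_corpus(generator_spec(n_pairs = 300, seed = 42,
                                         kg_fraction = 0.5))
kg <- train_transe(bundle$triples, d = 16, epochs = 100, seed = 42)
cfg <- model_config(hidden = 16, max_len = 64, char_dim = 8,
                    char_filters = 16, label_dim = 8, bcnn_filters = 8,
                    kg_dim = 16, ent2_dim = 16, mlp_hidden = 32)
train <- bundle$pairs[1:240, ]; test <- bundle$pairs[241:300, ]
model <- sts_model(train, bundle$lexicon, kg, cfg, seed = 42)
model <- train_sts(model, train,
                   train_config(lr = 0.01, epochs = 20, batch_size = 20,
                                seed = 42))
model
#> Multi-level STS model (sentence + char + entity I + entity II): fused dim 64, 13585 parameters
#>   trained 20 epochs, final loss 0.3071
evaluate_sts(model, test)$pcc
#> [1] 0.7618
```

The held-out PCC of 0.76 says the fused model recovers most of the
generator's graded-similarity signal from 240 training pairs. The
component ablation (`ablate()`) reports one PCC per configuration over
the seven standard settings: each entity variant and both, with and
without the character module, entity-free, and sentence-only. The
default configurations carry the reference hyperparameters (learning
rate 2e-5, 12 epochs, batch size 20, sequence length 380, d = 100,
kernel sizes 3, 50 BCNN filters, entity-I embedding dimension 50);
desk-scale runs override the learning rate because 2e-5 is a
fine-tuning rate for pretrained encoders.

A command-line interface wraps the same functions
(`inst/cli/stsfuse.R`): subcommands `synth`, `kg-train`, `train`,
`evaluate`, `predict`, `ablate`, each writing a manifest sufficient to
re-run it.

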