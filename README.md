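# entattn

Entity-aware gated self-attention transformers for clinical text
classification, in R.

## The problem

Free-text clinical questionnaires — concatenated question/answer pairs
describing symptoms, pain locations and known diseases — must be routed to
the right medical specialty. A plain transformer classifier sees only the
token stream; but a medical named-entity recogniser can tell it which
tokens *are* symptoms, locations or diseases, and the interaction between
those entities (which symptom occurs with which pain location) is exactly
what determines the appropriate department. This package implements an
encoder that injects that entity information in two places and provides
the full experimental apparatus around it: training, nested
cross-validation, confusion-matrix metrics including the multiclass
Matthews correlation coefficient (MCC), length-stratified evaluation,
ablations, and gate/attention introspection.

Because real questionnaire corpora are private, the package ships a
synthetic corpus generator with a *planted* entity co-occurrence rule, so
every mechanism can be validated end to end: when surface forms are fully
ambiguous, only a model that uses the supplied BIO tags can recover the
label.

## The model

Input sequences follow the standard layout
`[CLS] QA1 [SEP] QA2 ... [SEP]`, with a per-token entity type
`e ∈ {Symptom, Location, Disease, Others}` obtained from BIO tags.
Two mechanisms make the encoder entity-aware:

1. **Entity embedding layer.** The input representation of token *w* is
   the layer-normalised sum of four lookups:

   `e_w = e_w^token + e_w^pos + e_w^seg + e_w^entity`

2. **Gated entity-aware attention.** Each attention head computes two
   masked score matrices from the same scaled dot products
   `Q K' / sqrt(d_k)`: a *global* one whose additive mask removes only
   `[PAD]` positions, and a *local* one whose mask admits a pair (i, j)
   only when both tokens carry a medically relevant entity type. A
   per-token gate `g = sigmoid(h W_g + b_g)` fuses them convexly before
   the values are applied:

   `O_k = (g · S_k^local + (1 − g) · S_k^glob) V_k`

   Heads are concatenated, projected, and followed by the usual
   feed-forward network (4× expansion, exact GELU), residual connections
   and post-LN layer normalisation. Entity-aware attention can be enabled
   per layer; the `[CLS]` state feeds a softmax classification head.

Training uses AdamW (decoupled weight decay 1e-2), a linear schedule with
0.1 warm-up ratio, batch size 4, and keeps the epoch with the best
validation macro F1. The forward/backward pass is implemented in
C++ (RcppArmadillo) with an exactly matching — and independently tested —
R implementation of every operation.

## Worked example

Generate a corpus at full ambiguity (entity types recoverable only from
the tags), train the small profile, and evaluate:

```r
library(entattn)

gen  <- generator_config(n_samples = 800, ambiguity_rate = 1, seed = 42)
recs <- generate_corpus(gen)
recs[[1]]$units[[1]]
#> $tokens
#> [1] "q_7"   "amb_2" "w_4"   "amb_3" "w_18"  "w_13"
#> $bio_tags
#> [1] "O"     "B-LOC" "O"     "B-DIS" "O"     "O"

vocab <- corpus_vocabulary(recs)
fit <- train(recs[1:600], recs[601:700], vocab = vocab,
             config = small_config(vocab_size = vocab_size(vocab)),
             tconf = train_config(epochs = 4, seed = 42), max_len = 64)
fit
#> <entattn_fit> 2-layer model, best epoch 4 (dev macro F1 0.7993)

evaluate_model(fit, recs[701:800])
#> <metrics_report> n=100
#>   accuracy 0.7500 | macro P 0.7593 R 0.7570 F1 0.7488 | MCC 0.6729
```

Even this short run shows the gate separating medical from other tokens:

```r
subset(gate_summary(fit, recs[701:740]), group %in% c("MEDICAL", "OTHERS"))
#>    layer   group mean_gate n_tokens
#> 1      1  OTHERS 0.3269513     1201
#> 5      1 MEDICAL 0.4724965      356
#> 6      2  OTHERS 0.3116362     1201
#> 10     2 MEDICAL 0.4246163      356
```

With the full study conditions (2,500 training records, 6 epochs) the
entity-aware model reaches macro F1 ≈ 1.0 on held-out data while an
entity-blind ablation stays at chance; see below.

A command-line front end over the same functions lives at
`inst/cli/entattn.R` (verbs: `generate`, `train`, `nested-cv`, `ablate`,
`inspect-gates`, `inspect-attention`, `metrics`).

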