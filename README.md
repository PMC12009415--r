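# rehabminer

Mining rehabilitation knowledge from doctor–patient Q&A text.

Online health communities hold large volumes of patient questions and
doctor answers about rehabilitation: which symptoms point to which
disease, and which rehabilitation measures a doctor recommends — or warns
against — for it. `rehabminer` turns such records into structured
knowledge in three stages:

1. **Relation extraction.** Each candidate (disease, symptom) or
   (disease, measure) entity pair is turned into a position-marked
   instance — the first entity's span replaced by `#`, the second by `*`,
   serialized as `label@entity1$entity2$text`. A bidirectional GRU reads
   the token embeddings `X ∈ R^(L×D)` (defaults `L = 200`), concatenates
   the forward and backward states into `H ∈ R^(L×2u)` (`u = 32` hidden
   units per direction, so `H ∈ R^(200×64)`), and an attention layer pools
   it into a sentence vector:

   `M = tanh(H)`, `α = softmax(ωᵀM)`, `c = Hαᵀ ∈ R^64`,

   with padding positions masked out of the softmax. A softmax output
   layer classifies `c` into one of four relations: **DS** (symptom of
   disease), **SFD** (measure suitable for disease), **NSFD** (measure not
   suitable), **UKN** (no stated relation). Training minimises
   cross-entropy with Adam (batch 16, 40 epochs, learning rate 5e-4,
   dropout 0.2 on `H`), keeping the epoch with the best validation
   weighted F1.

2. **Knowledge dictionaries.** Predicted triples `(entity1, entity2,
   relation)` are organised into DS/SFD/NSFD dictionaries indexed by
   disease (UKN dropped, duplicates collapsed), exportable as JSON/CSV
   and as per-disease star graphs (GraphML/DOT). Measures listed as both
   suitable and unsuitable for the same disease are flagged as
   contradictions.

3. **Clustering.** Each dictionary's value lists are TF-IDF vectorised
   (smoothed idf, L2-normalised), PCA-reduced (components covering 95% of
   variance), and clustered with kmeans++ (D² seeding, Lloyd iterations,
   5 restarts, best inertia kept) at fixed k — defaults 15/20/6 for
   DS/SFD/NSFD — or a k grid scored by the mean silhouette coefficient
   `s = (b − a)/max(a, b)`.

Evaluation uses one-vs-rest precision, recall, F1, ROC AUC and
area-under-PR per class, aggregated by support-weighted averaging.

The original study corpora of this kind are rarely redistributable, so
the package ships a seeded synthetic-corpus generator
(`generate_corpus()`) that emulates the discourse structure — symptoms in
questions, diseases and cue-marked measures in answers, pronoun-style
follow-ups, cue-free noise sentences, and the strong DS:SFD:NSFD:UKN =
901:3602:497:235 class imbalance — with recoverable gold labels, so every
stage is testable end to end.

## Worked example

```r
library(rehabminer)

# 1. a synthetic Q&A corpus with planted relations
cfg <- generator_config(n_records = 800, noise_sentence_rate = 0.3,
                        seed = 42, max_len = 64)
corpus <- generate_corpus(cfg)
serialize_instance(corpus$gold[[1]])
#> "NSFD@dis34$tre42$w12 w3 w18 w50 w47 sym5 w65 w8 w30 w64 w21 w52 w40 w24 considering # unsuitable * w34 w22 w4 w17 it needs care"

# 2. train the BiGRU + attention classifier on a stratified 6:2:2 split
res <- run_extraction_experiment(cfg, model_cfg = model_config(seed = 42),
                                 D = 32, L = 64)
res$report
#>   class support precision    recall        f1      aupr       auc
#> 1    DS      26 0.9629630 1.0000000 0.9811321 1.0000000 1.0000000
#> 2   SFD     111 0.9736842 1.0000000 0.9866667 0.9995062 0.9988969
#> 3  NSFD      16 1.0000000 0.8750000 0.9333333 0.9653533 0.9947917
#> 4   UKN       7 1.0000000 0.7142857 0.8333333 0.8677812 0.9187675
#> 5 Total     160 0.9757249 0.9750000 0.9737256 0.9904082 0.9951599

# 3. extract triples from the records and build dictionaries
triples <- predict_triples(corpus$records, res$model)
dicts <- build_dictionaries(triples)
dictionary_sizes(dicts)
#>      kind n_diseases n_pairs
#> DS     DS         40     131
#> SFD   SFD         40     981
#> NSFD NSFD         34     156

# 4. cluster the suitable-measure dictionary
rep_ <- select_k_and_report(dicts$SFD, k = 6, seed = 42)
rep_$summary[1:3, c("category", "n_diseases", "shared_terms")]
#>   category n_diseases                      shared_terms
#> 1        1          8 tre32; sym10; sym27; tre27; tre33
#> 2        2          3  sym5; tre14; sym32; sym33; sym44
#> 3        3          8 sym53; sym10; sym21; sym37; tre15
```

The test rows read as: of 160 held-out instances the classifier
recovered almost all planted relations (weighted F1 0.974); the rarest
class (UKN, 7 instances) is hardest, as expected under this imbalance.
`dictionary_sizes()` counts how many diseases each dictionary indexes and
how many (disease, value) pairs it holds; the cluster summary lists, per
category, the diseases grouped together and the value phrases they share.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rehabminer", package="rehabminer"))')
Rscript $CLI generate --n 800 --noise 0.3 --seed 42 --out out/corpus
Rscript $CLI train    --annotations out/corpus/annotations.txt --len 64 --out out/model
Rscript $CLI extract  --corpus out/corpus/corpus.jsonl --model out/model/model.rds --out out/kb
Rscript $CLI cluster  --dict out/kb/sfd_dict.json --kind SFD --k 6 --out out/clusters
Rscript $CLI graph    --dict out/kb/ds_dict.json --kind DS --disease dis34 --out out/graphs
```

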