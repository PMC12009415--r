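Package: rehabminer
Title: Rehabilitation Knowledge Mining from Medical Q&A Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relation extraction over doctor-patient question-and-answer text
    using a bidirectional GRU encoder with attention pooling, organisation of
    the predicted (disease, entity, relation) triples into disease-symptom and
    suitable/unsuitable rehabilitation-measure dictionaries, and clustering of
    those dictionaries with TF-IDF vectorisation, PCA reduction, kmeans++ and
    silhouette-based model selection. Includes a seeded synthetic-corpus
    generator with planted, recoverable relation structure, one-vs-rest
    evaluation metrics (precision, recall, F1, AUC, AUPR), GraphML/DOT export
    of relation networks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
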