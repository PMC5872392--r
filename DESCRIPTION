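Package: henetrw
Title: Herb Target Prediction by Random Walk on a Heterogeneous Herb-Protein Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein targets of medicinal herbs by random walk with
    restart on a two-layer heterogeneous network: an herb layer weighted by
    efficacy-based cosine similarities, a protein layer weighted by
    pathway-based cosine similarities, and known herb-target links connecting
    the layers. Includes the PRINCE label-propagation baseline, leave-one-out
    evaluation under NoTarget and HalfTarget settings (precision, recall, F1,
    Hit@1), a similarity-bin overlap analysis with a Fisher-Yates shuffle
    null, shortest-path validation of candidate targets against a
    protein-protein interaction network, and a deterministic synthetic-data
    generator with planted module structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
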