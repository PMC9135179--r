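Package: eegdeep
Title: Swarm-Selected Autoencoder Features and a Q-Learning Decision Agent
    for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two deep-learning pipelines for binary classification of EEG
    recordings (seizure vs. background, schizophrenia vs. healthy). The first
    trains a sparse autoencoder with a Kullback-Leibler sparsity penalty,
    selects bottleneck features with a swarm optimizer (particle swarm, cuckoo
    search, or bat algorithm) wrapped around a budgeted classifier fitness, and
    classifies with a softmax deep neural network. The second builds decision
    states from a peephole bidirectional LSTM with additive attention and a
    child-sum Tree-LSTM, and trains a Q-learning agent that either commits to
    the recurrent head's prediction or defers to the tree representation.
    Includes a synthetic EEG generator, Bonn-style text and EDF readers,
    stratified k-fold evaluation with sensitivity/specificity/accuracy/good
    detection rate, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
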