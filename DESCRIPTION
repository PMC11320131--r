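Package: behavrec
Title: Behavioral Effect Classification and Corrective-Behavior
    Recommendation from Multimodal Health Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the effect of daily behaviors (sleep, heart-rate
    variability, motion, activity, blood markers) on health from
    multimodal wearable-style time series. Extracts a multidomain
    behavioral feature vector (Fourier, cosine, windowed-convolution,
    Gabor and Haar-wavelet components), selects features with a
    firefly-style stochastic optimizer driven by a dispersion
    (brightness) statistic, classifies records with an LSTM recurrence
    and softmax head quantized into low/medium/high effect levels, and
    derives corrective-behavior recommendations from a Pearson linkage
    map, fuzzy c-means clustering, an automatically derived minimum
    support, and Apriori frequent-itemset mining. Includes a seeded
    synthetic-data generator with planted class structure and
    cross-category correlations, recommendation-quality metrics, and a
    hyperparameter sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
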