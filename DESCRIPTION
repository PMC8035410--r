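Package: synaptoscope
Title: Synaptic Current Analysis: Event Detection, Kinetics, Fluctuation
    Analysis and Skew-t Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of inhibitory postsynaptic
    currents (IPSCs) recorded under voltage clamp: Bessel filtering and
    baseline handling for current traces, scaled-template event detection
    with rise/decay selection rules, per-event feature extraction (rise
    times, slopes, interevent intervals, burst windows), multi-exponential
    decay fitting with amplitude-weighted time constants and
    desensitization extents, paired-pulse re-sensitization curves,
    peak-scaled non-stationary fluctuation analysis estimating unitary
    current and receptor number from the parabolic variance-mean relation,
    and multivariate skew-t mixture clustering of amplitude-independent
    event features with BIC model selection.  A stochastic binomial
    channel-ensemble simulator of spontaneous IPSC trains and
    desensitizing paired-pulse protocols provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
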