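Package: perishift
Title: Circular-Shift Permutation Tests for Peri-Event Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of trial-aligned single-cell calcium imaging
    recorded during Pavlovian appetitive and fear conditioning. Implements a
    circular-shift permutation test with a population-pooled null and
    trial-summed Wilcoxon rank-sum statistics to label neurons as excited,
    inhibited or not significant with respect to conditioned and unconditioned
    stimuli; a per-trial sign-rank alternative; classification of
    cross-session-registered neurons into salience-encoding, valence-encoding
    and not-significant categories with contingency-table comparisons;
    peri-event z-scoring and summary metrics (AUC, time to peak, peak z);
    and a synthetic GCaMP-like trace simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    rhdf5,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
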