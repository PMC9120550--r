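Package: zaplinr
Title: Automatic Adaptive Removal of Frequency-Specific Noise from
    Multichannel Electrophysiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic removal of line noise and other oscillatory
    artifacts from continuous multichannel M/EEG recordings. Noise
    frequencies are detected as outlier peaks in the across-channel
    geometric-mean Welch spectrum, the recording is adaptively segmented
    into chunks of spatially stable noise topography via the stationarity
    of narrowband covariance matrices, and each chunk is cleaned with the
    Zapline algorithm (de Cheveigne 2020 <doi:10.1016/j.jneumeth.2019.108463>):
    a period-matched smoother splits the data into a spectrally clean part
    and a noise-band part, the noise part is spatially decomposed by joint
    decorrelation biased toward the noise frequency and its harmonics, the
    leading noise components are removed, and the parts are recombined
    without reducing the rank of the data. The number of removed components
    is chosen per chunk by iterative outlier detection on the component
    scores, and the whole procedure is re-run with adapted detection
    thresholds whenever the cleaned spectrum shows a residual peak or an
    introduced notch. Includes a ground-truthed synthetic data generator,
    EDF/binary/delimited-text I/O, diagnostic figures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    ggplot2,
    rlang,
    patchwork,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
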