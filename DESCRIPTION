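Package: epscat
Title: Optical Quantal Analysis of Synaptic Release from Line-Scan Calcium Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates synaptic release probability (p_r) by optical quantal
    analysis of line-scan (xt) calcium imaging at single dendritic spines.
    Converts raw line scans to background-corrected dF/F traces, classifies
    each stimulation trial as an all-or-none release success or failure using
    a noise-scaled threshold on the post-stimulus transient, screens for
    back-propagating action-potential and dendritic-spike contamination by
    comparing spine and dendrite signals, and summarises trials as a binomial
    release-probability estimate with standard error and confidence interval,
    paired-pulse facilitation metrics, pre/post-plasticity comparisons and
    trial-number planning. A synthetic line-scan generator with known ground
    truth (stochastic uniquantal events, facilitation, contamination, Poisson
    shot noise, bleaching) makes every stage of the pipeline verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LineScanRecord.R'
    'SimParams.R'
    'cli.R'
    'detect.R'
    'epscat-package.R'
    'estimate.R'
    'extract.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
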