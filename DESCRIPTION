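Package: dropgate
Title: Gating and Poisson Quantification of Two-Channel Droplet Digital PCR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing two-channel droplet digital PCR (ddPCR)
    experiments in which droplets fall into four classes: negative in both
    channels (NN), positive only in Channel 1 (PN), positive only in Channel 2
    (NP), and positive in both (PP). Droplet amplitude files exported from the
    instrument software are read into a plate model; droplets are gated by
    linear thresholds, four-centre k-means, or k-nearest neighbours; ambiguous
    intermediate droplets ("rain") are removed by per-cluster standard
    deviation bounds or squared Mahalanobis ellipses that account for cluster
    rotation; and target concentrations (copies per microlitre) and mutant
    fractional abundance are estimated from gated counts by Poisson occupancy
    statistics. A synthetic-data generator with known ground truth and a
    command-line interface support reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
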