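Package: chromodyn
Title: Chromatin Domain Mobility Analysis for Live-Cell 3D Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the mobility of replication-labeled chromatin domains
    in 3D live-cell fluorescence movies. Provides drift correction by joint
    affine and non-rigid 3D registration of the DNA channel, spot-enhancing
    (Laplacian-of-Gaussian) focus detection with automatic thresholding,
    Kalman-predicted globally-optimal trajectory linking, mean-square
    displacement analysis with short-range diffusion (6Dt + b) and anomalous
    diffusion (6*Gamma*t^alpha) model fits, radius-of-gyration confinement
    measures, chromatin compaction classification (2-class Gaussian mixture
    and 7-class Potts-regularized maps), nuclear morphometry, and
    full-width-at-half-maximum resolution-gain analysis for matched
    confocal/STED image pairs. A synthetic-movie generator with known
    ground truth (Brownian and fractional-Brownian foci, PSF blur,
    Poisson-Gaussian noise, photobleaching, global cell motion) makes every
    stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
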