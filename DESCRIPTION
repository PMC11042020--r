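Package: eit3d
Title: Three-Dimensional Electrical Impedance Tomography with Residual
    Network Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end three-dimensional electrical impedance tomography
    (EIT) at desk scale: a complete-electrode-model finite element forward
    solver on structured tetrahedral cylinder meshes with a 48-electrode,
    three-ring adjacent stimulation protocol; conductivity phantom
    generators (acrylic inclusions and smooth gradient fields emulating a
    maize ear); SNR-controlled Gaussian noise injection with
    detection-limit accounting; reconfiguration of 2,160-value boundary
    voltage frames into 45 x 48 single-channel feature maps; a residual
    bottleneck regression network mapping feature maps to per-element
    conductivity; a regularized Gauss-Newton absolute-imaging baseline;
    and a metric suite (RMSE, correlation coefficient, SSIM, and the
    distribution-similarity statistics MMD, KDE-ISE, LMMD and KNNDC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
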