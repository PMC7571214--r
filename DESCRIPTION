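Package: endodepth
Title: Photometric-Stereo Depth Map Reconstruction for Monocular Capsule
    Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs metric depth maps of the digestive-tract surface
    from four monocular images, each lit by one known near-point LED, as used
    in magnetically actuated capsule endoscopy.  The depth of the specular
    highlight created by one light is estimated by combining the mirror
    reflection constraint with Lambertian image-ratio equations, and the
    whole-surface depth map is then integrated outward from that seed with a
    forward upwind fast-marching scheme.  Includes a synthetic endoscopic
    scene renderer (Blinn-Phong polyp on a plane under four near-point
    lights) for offline validation, highlight detection, radiometric response
    inversion, and RMSE evaluation against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
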