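Package: phfluxnet
Title: Single-Cell Proton Flux Inference and Exchange Networks from
    Extracellular pH Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts sparse, noisy extracellular pH measurements and cell
    positions into per-cell proton exchange fluxes over time, and then into a
    weighted directed cell-to-cell exchange network. The stationary proton
    concentration field is modelled as a superposition of point-source
    (monopole) solutions of the Laplace equation plus a frame-boundary term;
    per-cell fluxes are inferred by Tikhonov-regularized maximum likelihood
    using a Gauss-Newton warm start, Metropolis-Hastings sampling of the
    posterior, and simulated annealing for the maximum a posteriori estimate.
    Pairwise exchange fluxes between acid-exporting and acid-importing cells
    are derived from diffusive absorption probabilities and summarised with
    standard graph statistics (average and maximum degree, largest connected
    component, Poisson null for the degree distribution). Includes a synthetic
    experiment generator emulating time-lapse pH-sensing scaffold data and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
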