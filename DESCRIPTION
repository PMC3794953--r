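Package: dmrimc
Title: Monte Carlo Simulation of Water Diffusion for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A random-walk Monte Carlo engine for water diffusion in
    triangle-mesh models of neural tissue, coupled to an MR signal
    synthesizer. Builds parametric substrates (sphere and cylinder
    lattices, crossing/kissing/branching fiber phantoms), simulates
    Brownian walkers with membrane permeability, specular reflection and
    an optional slow-diffusion polar membrane layer, constructs effective
    gradient waveforms for a catalogue of diffusion pulse sequences
    (PGSE, multiple PGSE, stimulated-echo variants, twice-refocused spin
    echo, oscillating gradients), synthesizes noisy diffusion-weighted
    images, and analyzes them with diffusion-tensor, biexponential and
    q-space diffraction models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
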