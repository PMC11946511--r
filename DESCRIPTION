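Package: eseemr
Title: Simulation and Analysis of 3-Pulse ESEEM and HYSCORE Pulsed EPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electron spin echo envelope modulation (3-pulse ESEEM)
    and hyperfine sublevel correlation (HYSCORE) experiments for S = 1/2
    centers such as Cu(2+) coupled to mixtures of 15N (I = 1/2) and 14N
    (I = 1) nuclei.  Implements the manifold product rule extended to
    multiple equivalent I = 1/2 nuclei (the 2*nu_alpha combination line of
    multi-histidine coordination), exact-cancellation 14N nuclear quadrupole
    frequencies, general sub-Hamiltonian (Mims trace) engines with powder
    averaging, a full brute-force density-matrix oracle, the standard
    post-acquisition processing chain (normalization, exponential background
    subtraction, Chebyshev apodization, zero-filling, magnitude FFT, peak
    picking), tau blind-spot calculators and joint 14N/15N acquisition
    parameter optimization, plus file I/O for two-column ASCII, CSV matrices
    and minimal Bruker BES3T traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
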