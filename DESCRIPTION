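Package: cardiovib
Title: Cardiac Multi-Frequency Vibration Simulation and Fiducial-Point Extraction
Version: 0.1.0
Authors@R:
    person("Vibration", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with multi-frequency chest-wall vibration
    recordings (mechanocardiography). Provides an event-based Fourier-atom
    simulator of synchronized ECG and composite vibration channels at 2 kHz,
    zero-phase Butterworth band decomposition into ULF-SCG (1-5 Hz),
    SCG (5-30 Hz) and PCG (20-200 Hz), empirical mode decomposition for
    model validation, R-wave anchored cardiac-cycle segmentation into
    fixed-length labeled windows, Shannon-energy based automatic labeling of
    the S1/S2 heart sounds, a compact 1D convolutional network for
    coordinate regression of ten fiducial points per cycle, and the
    accompanying evaluation protocol (R-squared, MAE, RMSE, repeated
    random splits and k-fold cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
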