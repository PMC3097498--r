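#' Bundled example: microwave-assisted alkali degradation of rebamipide
#'
#' A published-style 2^3 forced-degradation experiment on the antiulcer
#' drug rebamipide: NaOH normality (0.1/1 N), irradiation time
#' (15/30 min) and microwave power (420/700 W), with percent degradation
#' observed in all eight runs. Shipped as a plain CSV under
#' `inst/extdata/` together with its factor configuration.
#'
#' @return `example_degradation_factors()`: list of three [fd_factor]
#'   objects. `example_degradation_design()`: a `factorial_design` with
#'   responses attached, standard order.
#' @export
example_degradation_factors <- function() {
  read_factor_config(system.file("extdata", "rebamipide_alkali_factors.json",
                                 package = "fdopt", mustWork = TRUE))
}

#' @rdname example_degradation_factors
#' @export
example_degradation_design <- function() {
  read_design_csv(system.file("extdata", "rebamipide_alkali_design.csv",
                              package = "fdopt", mustWork = TRUE),
                  factors = example_degradation_factors())
}

#' Bundled example: recovery panels for accuracy/precision
#'
#' Placebo spiked at 80, 100 and 120 mg (80-120% of label claim),
#' analysed in triplicate on three days; amount-found values in mg.
#'
#' @return Named list of `recovery_panel` objects (see
#'   [anova_precision()]).
#' @export
example_recovery_panels <- function() {
  read_recovery_csv(system.file("extdata", "rebamipide_recovery.csv",
                                package = "fdopt", mustWork = TRUE))
}

#' Bundled example: synthetic calibration data
#'
#' Noise-free concentration/peak-area pairs generated from the reported
#' rebamipide calibration line (slope 601211, intercept 41127) over
#' 0.5-5 micrograms per mL. Synthetic: raw areas were never published,
#' so these exist only to exercise the calibration fit.
#'
#' @return Data frame with columns `concentration`, `area`.
#' @export
example_calibration_synthetic <- function() {
  read_calibration_csv(system.file("extdata", "calibration_synthetic.csv",
                                   package = "fdopt", mustWork = TRUE))
}
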