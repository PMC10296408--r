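#' Construct a simulation configuration
#'
#' Central constructor for [SimulationConfig-class]. Defaults describe a
#' typically developing (TD) child under the package's study conditions:
#' a 20 uM evoked OHb peak with a -1/3 DHb counterpart lagged 1 s, 25%
#' between-subject amplitude variability, a 1.5x right-hemisphere gain
#' with modest subject-level jitter, and physiological noise (cardiac
#' 1.1 Hz, respiration 0.3 Hz, Mayer waves 0.1 Hz), slow random-walk
#' drift and white noise. Use [tdSimulationConfig()] and
#' [asdSimulationConfig()] for the two cohort conditions.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param amplitude_ohb Mean evoked OHb peak (mol/L, > 0).
#' @param amplitude_dhb Mean evoked DHb peak (mol/L, <= 0); default
#'   `-amplitude_ohb / 3`.
#' @param amplitude_sd Between-subject SD of the OHb amplitude (mol/L).
#' @param lateralization Right-hemisphere gain (> 0; 1 = no asymmetry).
#' @param lateralization_sd SD of the mean-one log-normal subject jitter
#'   on the gain.
#' @param dhb_lag_s Lag of the DHb response behind OHb (s).
#' @param noise Named amplitudes: `cardiac`, `respiratory`, `mayer`
#'   (sinusoids, mol/L), `drift` (random-walk step SD per sample),
#'   `white` (per-sample Gaussian SD).
#' @param dhb_noise_scale Factor applied to all noise components on the
#'   DHb series.
#' @param artifact_rate Motion artifacts per minute.
#' @param spike_mag,shift_mag Artifact magnitudes in OD units.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(sampling_rate = 10.2,
                             amplitude_ohb = 2e-5,
                             amplitude_dhb = -amplitude_ohb / 3,
                             amplitude_sd = 5e-6,
                             lateralization = 1,
                             lateralization_sd = 0,
                             dhb_lag_s = 1,
                             noise = c(cardiac = 1e-6, respiratory = 8e-7,
                                       mayer = 1e-6, drift = 2e-8,
                                       white = 5e-7),
                             dhb_noise_scale = 1 / 3,
                             artifact_rate = 1.2,
                             spike_mag = 1.0,
                             shift_mag = 0.5) {
  new("SimulationConfig",
      sampling_rate = sampling_rate,
      amplitude_ohb = amplitude_ohb,
      amplitude_dhb = amplitude_dhb,
      amplitude_sd = amplitude_sd,
      lateralization = lateralization,
      lateralization_sd = lateralization_sd,
      dhb_lag_s = dhb_lag_s,
      noise = noise,
      dhb_noise_scale = dhb_noise_scale,
      artifact_rate = artifact_rate,
      spike_mag = spike_mag,
      shift_mag = shift_mag)
}

#' Study-condition configurations for the two cohorts
#'
#' `tdSimulationConfig()` encodes the typically developing group: full
#' response amplitude and a rightward-lateralised response
#' (right-hemisphere gain 1.5, i.e. a true laterality index of -0.2 under
#' the sign convention where negative means rightward dominance).
#' `asdSimulationConfig()` encodes the ASD group: a 40% lower mean OHb
#' amplitude, no mean lateralization (gain 1), and twice the
#' subject-level gain variability, producing the reduced and more
#' variable lateralization the analysis is designed to detect.
#'
#' @param ... Overrides passed to [simulationConfig()].
#' @return A [SimulationConfig-class].
#' @rdname cohortConfigs
#' @export
tdSimulationConfig <- function(...) {
  args <- list(amplitude_ohb = 2e-5, lateralization = 1.5,
               lateralization_sd = 0.15)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

#' @rdname cohortConfigs
#' @export
asdSimulationConfig <- function(...) {
  args <- list(amplitude_ohb = 1.2e-5, lateralization = 1.0,
               lateralization_sd = 0.3)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

#' Clinical score generation model
#'
#' Parameters of the synthetic clinical table for the ASD cohort. The
#' autism-quotient total (AQ_tot) is generated as a monotone (linear)
#' function of the subject's true laterality index plus Gaussian noise:
#' `AQ = aq_intercept + aq_slope * LI + N(0, aq_sd)`. With `aq_slope > 0`
#' a weaker rightward bias (LI closer to 0 or positive) yields a higher
#' AQ, i.e. AQ and LI are positively correlated. The remaining scores
#' (ADOS total and comparison, non-verbal IQ, Vineland total) are drawn
#' independently of the response, with means and SDs in the range of the
#' package's reference clinical table.
#'
#' @param aq_intercept,aq_slope,aq_sd AQ model parameters.
#' @param ados_tot_mean,ados_tot_sd ADOS total score distribution.
#' @param ados_comp_mean,ados_comp_sd ADOS comparison score distribution.
#' @param nv_iq_mean,nv_iq_sd Non-verbal IQ distribution.
#' @param vabs_mean,vabs_sd Vineland total score distribution.
#' @param ages Integer ages (years) sampled uniformly per subject.
#' @return A named list of class `clinical_model`.
#' @export
clinicalModel <- function(aq_intercept = 55, aq_slope = 120, aq_sd = 6,
                          ados_tot_mean = 12, ados_tot_sd = 2.6,
                          ados_comp_mean = 5.5, ados_comp_sd = 1,
                          nv_iq_mean = 104, nv_iq_sd = 14,
                          vabs_mean = 84, vabs_sd = 11,
                          ages = 3:6) {
  assertScalarNumeric(aq_sd, "aq_sd", lower = 0)
  structure(
    list(aq_intercept = aq_intercept, aq_slope = aq_slope, aq_sd = aq_sd,
         ados_tot_mean = ados_tot_mean, ados_tot_sd = ados_tot_sd,
         ados_comp_mean = ados_comp_mean, ados_comp_sd = ados_comp_sd,
         nv_iq_mean = nv_iq_mean, nv_iq_sd = nv_iq_sd,
         vabs_mean = vabs_mean, vabs_sd = vabs_sd, ages = ages),
    class = "clinical_model"
  )
}
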