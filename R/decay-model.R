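#' Two-state relaxed decay model
#'
#' Normalized Mant-ATP chase fluorescence as a function of time after the
#' unlabeled-ATP chase. The fast phase (amplitude `P1`, time constant `T1`)
#' tracks myosin heads in the disordered-relaxed (DRX) state; the slow phase
#' (`P2`, `T2`) tracks the super-relaxed (SRX) state:
#'
#' \deqn{F(t) = 1 - P_1 (1 - e^{-t/T_1}) - P_2 (1 - e^{-t/T_2})}
#'
#' with amplitudes in percent of the T = 0 fluorescence. The curve starts at
#' exactly 1 and decays towards the plateau `1 - (P1 + P2)/100`.
#'
#' @param t Time in seconds (vector).
#' @param P1,P2 Fast (DRX) and slow (SRX) amplitudes, in percent.
#' @param T1,T2 Fast and slow time constants, in seconds.
#' @return Numeric vector of normalized fluorescence values.
#' @examples
#' decay_model(c(0, 30, 300), P1 = 25, T1 = 20, P2 = 45, T2 = 230)
#' @export
decay_model <- function(t, P1, T1, P2, T2) {
  if (any(!is.finite(c(P1, T1, P2, T2))) || T1 <= 0 || T2 <= 0) {
    stop_invalid("decay_model() needs finite amplitudes and positive time constants.")
  }
  1 - P1 / 100 * (1 - exp(-t / T1)) - P2 / 100 * (1 - exp(-t / T2))
}

#' Standard Mant-ATP acquisition grid
#'
#' Frame times for the standard chase protocol: one frame every 5 s for the
#' first 90 s, then every 10 s out to 300 s (40 frames in total, starting at
#' the T = 0 washout image).
#'
#' @return Numeric vector of frame times in seconds.
#' @examples
#' length(mant_atp_grid()) # 40
#' @export
mant_atp_grid <- function() {
  c(seq(0, 90, by = 5), seq(100, 300, by = 10))
}
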