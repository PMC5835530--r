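#' Generate a vestibular stimulation waveform
#'
#' Builds the two stimulus types used in the galvanic vestibular stimulation
#' (GVS) design: a stochastic ("noisy") waveform, zero-mean with a 1/f power
#' spectrum confined to 0.1-10 Hz, and a pure 1 Hz sinusoid.  The noisy
#' waveform is synthesized in the frequency domain with deterministic
#' amplitudes (proportional to \eqn{1/\sqrt{f}} inside the band, zero
#' outside) and uniformly random phases, so its periodogram follows the 1/f
#' target by construction.  Both waveforms are scaled to unit peak amplitude;
#' in the experiment amplitude is set per subject relative to sensory
#' threshold, so only the shape matters here.
#'
#' @param kind `"noisy"` or `"sinusoidal"`.
#' @param duration Waveform duration in seconds.
#' @param sample_rate Sampling rate in Hz.  For `"noisy"` it must exceed
#'   20 Hz so that the 10 Hz band edge is representable.
#' @param rng_seed Integer seed controlling the random phases (ignored for
#'   the sinusoid).
#' @param band Length-2 passband in Hz for the noisy stimulus.
#' @param freq Sinusoid frequency in Hz.
#' @return Numeric vector of length `round(duration * sample_rate)` with
#'   attributes `sample_rate` and `kind`.
#' @examples
#' s <- generate_stimulus("sinusoidal", duration = 10, sample_rate = 100)
#' g <- generate_stimulus("noisy", duration = 60, sample_rate = 100,
#'                        rng_seed = 7)
#' @export
generate_stimulus <- function(kind = c("noisy", "sinusoidal"), duration,
                              sample_rate, rng_seed = 1L,
                              band = c(0.1, 10), freq = 1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) ppn_config_error(
                     "invalid stimulus kind; use 'noisy' or 'sinusoidal'"))
  if (!is.numeric(duration) || duration <= 0)
    ppn_config_error("duration must be positive")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    ppn_config_error("sample_rate must be positive")
  n <- round(duration * sample_rate)
  if (kind == "sinusoidal") {
    tt <- seq_len(n) / sample_rate
    x <- sin(2 * pi * freq * tt)
  } else {
    if (sample_rate <= 2 * band[2])
      ppn_config_error(sprintf(
        "sample_rate %.3g Hz too low for the %.3g Hz band edge", sample_rate,
        band[2]))
    x <- with_seed(rng_seed, function() {
      freqs <- seq_len(floor(n / 2)) * sample_rate / n
      amp <- ifelse(freqs >= band[1] & freqs <= band[2], 1 / sqrt(freqs), 0)
      phase <- stats::runif(length(freqs), 0, 2 * pi)
      spec <- complex(real = rep(0, n))
      half <- amp * exp(1i * phase)
      spec[2:(length(freqs) + 1L)] <- half
      # Hermitian symmetry for a real signal (drop Nyquist bin if n even).
      idx <- 2:(length(freqs) + 1L)
      mirror <- n + 2L - idx
      keep <- mirror > length(freqs) + 1L
      spec[mirror[keep]] <- Conj(half[keep])
      Re(stats::fft(spec, inverse = TRUE)) / n
    })
    x <- x - mean(x)
  }
  x <- x / max(abs(x))
  attr(x, "sample_rate") <- sample_rate
  attr(x, "kind") <- kind
  x
}
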