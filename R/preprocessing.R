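#' Epoching, band-pass filtering and instantaneous phase
#'
#' Continuous source time series (sources x samples) are segmented into
#' fixed-length epochs, band-pass filtered with a zero-phase FIR applied on
#' windows padded with real neighbouring signal, and converted to
#' instantaneous phase via the analytic signal.
#'
#' @name preprocessing
NULL

#' Frequency band definition
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return an object of class `plv_band`.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo))
    stop(sprintf("invalid band '%s': need 0 < lo < hi", name))
  structure(list(name = name, lo = lo, hi = hi), class = "plv_band")
}

#' Default analysis bands
#'
#' Alpha-mu 8-13 Hz, low beta 12-20 Hz, upper beta 20-30 Hz.
#' @return named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(alpha_mu   = band_spec("alpha_mu", 8, 13),
       low_beta   = band_spec("low_beta", 12, 20),
       upper_beta = band_spec("upper_beta", 20, 30))
}

new_epoch_set <- function(data, fs, epoch_len, band = "broadband",
                          subject_id = NA_character_) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, fs = fs, epoch_len = epoch_len, band = band,
                 subject_id = subject_id,
                 n_sources = dim(data)[1], n_epochs = dim(data)[2],
                 n_samples = dim(data)[3]),
            class = "plv_epochs")
}

#' @export
print.plv_epochs <- function(x, ...) {
  bn <- if (inherits(x$band, "plv_band"))
    sprintf("%s [%g-%g Hz]", x$band$name, x$band$lo, x$band$hi) else x$band
  cat(sprintf("Epoch set: %d sources x %d epochs x %d samples (fs %g Hz, %s)\n",
              x$n_sources, x$n_epochs, x$n_samples, x$fs, bn))
  invisible(x)
}

#' Segment a continuous recording into epochs
#'
#' Consecutive, non-overlapping windows of `epoch_len` seconds are taken from
#' sample 1 onwards; a trailing partial window is discarded.
#'
#' @param x numeric matrix, sources x samples (a vector is treated as one
#'   source).
#' @param fs sampling rate in Hz.
#' @param epoch_len epoch length in seconds (default 4).
#' @param max_epochs keep at most this many epochs (default all).
#' @param subject_id optional label carried through.
#' @return a broadband `plv_epochs`.
#' @export
segment_epochs <- function(x, fs, epoch_len = 4, max_epochs = Inf,
                           subject_id = NA_character_) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  spp <- round(epoch_len * fs)
  n_ep <- floor(ncol(x) / spp)
  if (n_ep < 1)
    stop(sprintf("recording too short: %d samples < one %g-s epoch",
                 ncol(x), epoch_len))
  n_ep <- min(n_ep, max_epochs)
  dat <- array(x[, seq_len(n_ep * spp), drop = FALSE],
               dim = c(nrow(x), spp, n_ep))
  new_epoch_set(aperm(dat, c(1, 3, 2)), fs, epoch_len,
                subject_id = subject_id)
}

#' Design a zero-phase band-pass FIR
#'
#' Type-I (odd length, symmetric) FIR band-pass via a Kaiser window, designed
#' for a single-pass stop-band attenuation `atten_db` over a transition of
#' `trans_width` Hz (default `lo / 2`, so that the stop band is reached one
#' octave below the low edge). The filter is meant to be applied through its
#' squared magnitude response (see [bandpass_epochs()]), which doubles the
#' stop-band attenuation in dB and makes the net phase response exactly zero.
#'
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param atten_db single-pass design attenuation in dB (default 26).
#' @param trans_width transition width in Hz (default `band$lo / 2`).
#' @return list with `h` (coefficients), `band`, `fs`.
#' @export
design_bandpass_fir <- function(band, fs, atten_db = 26, trans_width = NULL) {
  stopifnot(inherits(band, "plv_band"))
  if (band$hi >= fs / 2)
    stop(sprintf("band '%s' upper edge %g Hz >= Nyquist (fs = %g Hz)",
                 band$name, band$hi, fs))
  if (is.null(trans_width)) trans_width <- band$lo / 2
  ord <- ceiling((atten_db - 7.95) / (2.285 * 2 * pi * trans_width / fs))
  if (ord %% 2 == 1) ord <- ord + 1
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 +
    0.07886 * (atten_db - 21)
  else 0
  h <- signal::fir1(ord, c(band$lo, band$hi) / (fs / 2), type = "pass",
                    window = signal::kaiser(ord + 1, beta))
  list(h = as.numeric(h), band = band, fs = fs)
}

# |H(f)|^2 sampled on the n FFT bins of a length-n window.
fir_mag2 <- function(h, n) {
  if (length(h) > n) stop("window shorter than filter; increase padding")
  Mod(fft(c(h, rep(0, n - length(h)))))^2
}

# Analytic-signal weights for a length-n FFT.
analytic_weights <- function(n) {
  w <- numeric(n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else w[2:((n + 1) / 2)] <- 2
  w
}

# Zero-phase filter columns of a matrix (samples x channels) in the FFT
# domain, optionally converting to the analytic signal in the same pass.
fft_filter <- function(x, mag2, analytic = FALSE) {
  n <- nrow(x)
  w <- if (analytic) mag2 * analytic_weights(n) else mag2
  y <- mvfft(mvfft(x) * w, inverse = TRUE) / n
  if (analytic) y else Re(y)
}

# Padded-window bounds for each epoch; pads shrink at the recording edges.
epoch_windows <- function(n_samples, spp, n_ep, pad_n) {
  t(vapply(seq_len(n_ep), function(e) {
    s <- (e - 1) * spp + 1
    c(start = s, end = s + spp - 1,
      pre = min(pad_n, s - 1), post = min(pad_n, n_samples - (s + spp - 1)))
  }, numeric(4)))
}

#' Band-pass filter a continuous recording into epochs
#'
#' Epoch boundaries are those of [segment_epochs()]. Each epoch is filtered
#' on a window padded with `pad` seconds of the real neighbouring recording
#' on both sides; where the recording ends inside the pad, the missing part
#' is reflection-padded and a warning is issued. The filter is applied as the
#' squared magnitude response of a FIR in the frequency domain, i.e. exactly
#' zero-phase (phase relations, which PLV measures, are untouched). The
#' central `epoch_len` seconds of each window are returned.
#'
#' @inheritParams segment_epochs
#' @param band a [band_spec()].
#' @param pad pad length in seconds on each side (default 2).
#' @param fir optional filter from [design_bandpass_fir()]; designed on the
#'   fly otherwise.
#' @param analytic return the complex analytic signal instead of the real
#'   filtrate (one FFT pass; used by the phase pipeline).
#' @return a `plv_epochs` in the given band (complex-valued if
#'   `analytic = TRUE`).
#' @export
bandpass_epochs <- function(x, fs, band, epoch_len = 4, pad = 2,
                            max_epochs = Inf, fir = NULL,
                            subject_id = NA_character_, analytic = FALSE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(inherits(band, "plv_band"))
  if (is.null(fir)) fir <- design_bandpass_fir(band, fs)
  spp <- round(epoch_len * fs)
  n_ep <- min(floor(ncol(x) / spp), max_epochs)
  if (n_ep < 1) stop("recording too short for one epoch")
  pad_n <- round(pad * fs)
  win <- epoch_windows(ncol(x), spp, n_ep, pad_n)
  short <- win[, "pre"] < pad_n | win[, "post"] < pad_n
  if (any(short))
    warning(sprintf(paste0("%d epoch(s) at the recording boundary had less ",
                           "than %g s of real padding; reflection-padded"),
                    sum(short), pad), call. = FALSE)
  out <- array(if (analytic) complex(1) else 0,
               dim = c(nrow(x), n_ep, spp))
  full_len <- spp + 2 * pad_n
  mag2_full <- fir_mag2(fir$h, full_len)
  for (e in seq_len(n_ep)) {
    pre <- win[e, "pre"]; post <- win[e, "post"]
    seg <- x[, (win[e, "start"] - pre):(win[e, "end"] + post), drop = FALSE]
    if (pre < pad_n || post < pad_n) {  # reflect the missing pad
      need_pre <- pad_n - pre; need_post <- pad_n - post
      nc <- ncol(seg)
      left <- if (need_pre > 0)
        seg[, pmin(nc, need_pre:1 + 1), drop = FALSE] else NULL
      right <- if (need_post > 0)
        seg[, pmax(1, nc - seq_len(need_post)), drop = FALSE] else NULL
      seg <- cbind(left, seg, right)
    }
    y <- fft_filter(t(seg), mag2_full, analytic = analytic)
    out[, e, ] <- t(y[(pad_n + 1):(pad_n + spp), , drop = FALSE])
  }
  new_epoch_set(out, fs, epoch_len, band = band, subject_id = subject_id)
}

#' Instantaneous phase of band-limited epochs
#'
#' Phase of the analytic signal (Hilbert-transform method), computed per
#' source and epoch, wrapped to (-pi, pi].
#'
#' @param epochs a band-limited `plv_epochs` (real- or complex-valued).
#' @return a `plv_phase` object of the same shape.
#' @export
instantaneous_phase <- function(epochs) {
  stopifnot(inherits(epochs, "plv_epochs"))
  d <- epochs$data
  if (!all(is.finite(Mod(d))))
    stop("non-finite values in epochs")
  dm <- dim(d)
  if (is.complex(d)) {
    m <- Mod(d)
    dim(m) <- dm
    if (any(rowSums(m, dims = 2) == 0))
      stop("undefined phase: all-zero epoch")
    ph <- Arg(d)
  } else {
    ph <- array(0, dm)
    for (e in seq_len(dm[2])) {
      seg <- t(matrix(d[, e, ], dm[1], dm[3]))   # samples x sources
      if (any(colSums(abs(seg)) == 0))
        stop("undefined phase: all-zero epoch")
      a <- mvfft(mvfft(seg) * analytic_weights(dm[3]), inverse = TRUE) / dm[3]
      ph[, e, ] <- t(Arg(a))
    }
  }
  # Arg returns (-pi, pi]; map any -pi representation onto pi
  ph[ph <= -pi] <- pi
  structure(list(data = ph, fs = epochs$fs, epoch_len = epochs$epoch_len,
                 band = epochs$band, subject_id = epochs$subject_id,
                 n_sources = dm[1], n_epochs = dm[2], n_samples = dm[3]),
            class = "plv_phase")
}

#' Band-limited instantaneous phases in one pass
#'
#' Fast path used by the pipeline: the whole continuous recording is
#' filtered and converted to the analytic signal in a single FFT per source
#' (so every interior epoch is effectively padded with all available real
#' signal, a superset of the 2-s contract), then segmented and reduced to
#' phase. The recording ends are reflection-padded by `pad` seconds to
#' suppress circular-convolution wrap-around; as with [bandpass_epochs()],
#' a warning notes that boundary epochs lack real padding. Numerically
#' equivalent (interior samples) to
#' `instantaneous_phase(bandpass_epochs(...))` and without the epoch-edge
#' effects of a per-epoch Hilbert transform.
#'
#' @inheritParams bandpass_epochs
#' @return a `plv_phase`.
#' @export
band_phases <- function(x, fs, band, epoch_len = 4, pad = 2,
                        max_epochs = Inf, fir = NULL,
                        subject_id = NA_character_) {
  firs <- list(fir)
  names(firs) <- band$name
  band_phases_multi(x, fs, setNames(list(band), band$name),
                    epoch_len = epoch_len, pad = pad,
                    max_epochs = max_epochs, firs = firs,
                    subject_id = subject_id)[[1]]
}

#' Band-limited phases for several bands sharing one forward FFT
#'
#' Same computation as [band_phases()] for each band; the forward transform
#' of the padded recording is computed once and reused for every band.
#'
#' @inheritParams band_phases
#' @param bands named list of [band_spec()]s.
#' @param firs optional named list of filters from [design_bandpass_fir()].
#' @param phase_array keep the sources x epochs x samples phase array in
#'   `$data` (default). `FALSE` retains only the unit-phasor matrix the PLV
#'   kernel consumes, halving memory and skipping one trig pass; downstream
#'   PLV results are identical.
#' @return named list of `plv_phase` objects, one per band.
#' @export
band_phases_multi <- function(x, fs, bands, epoch_len = 4, pad = 2,
                              max_epochs = Inf, firs = NULL,
                              subject_id = NA_character_,
                              phase_array = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(length(bands) >= 1)
  spp <- round(epoch_len * fs)
  n_ep <- min(floor(ncol(x) / spp), max_epochs)
  if (n_ep < 1) stop("recording too short for one epoch")
  pad_n <- round(pad * fs)
  n_used <- n_ep * spp
  if (pad_n > 0)
    warning(sprintf(paste0("epoch(s) at the recording boundary had less ",
                           "than %g s of real padding; reflection-padded"),
            pad), call. = FALSE)
  xt <- t(x[, seq_len(min(ncol(x), n_used + pad_n)), drop = FALSE])
  nr <- nrow(xt)
  left <- if (pad_n > 0) xt[pmin(nr, (pad_n + 1):2), , drop = FALSE] else NULL
  need_post <- max(0, n_used + pad_n - nr)
  right <- if (need_post > 0)
    xt[pmax(1, nr - seq_len(need_post)), , drop = FALSE] else NULL
  xp <- rbind(left, xt, right)
  n <- nrow(xp)
  X <- mvfft(xp)
  aw <- analytic_weights(n)
  out <- lapply(names(bands), function(bn) {
    band <- bands[[bn]]
    stopifnot(inherits(band, "plv_band"))
    fir <- if (!is.null(firs) && !is.null(firs[[bn]])) firs[[bn]] else
      design_bandpass_fir(band, fs)
    w <- fir_mag2(fir$h, n) * aw
    a <- mvfft(X * w, inverse = TRUE) / n
    a <- a[(pad_n + 1):(pad_n + n_used), , drop = FALSE]  # samples x sources
    mu <- Mod(a)
    zero <- mu == 0
    if (any(zero)) {
      mm <- mu; dim(mm) <- c(spp, n_ep * nrow(x))
      if (any(colSums(mm) == 0)) stop("undefined phase: all-zero epoch")
      mu[zero] <- 1
    }
    # unit phasor exp(i * phase), sources x samples (epoch blocks
    # contiguous): the PLV kernel consumes this directly
    u <- t(a / mu)
    if (any(zero)) u[t(zero)] <- 1 + 0i   # Arg(0) is 0, so the phasor is 1
    ph <- NULL
    if (phase_array) {
      ph <- aperm(array(Arg(a), dim = c(spp, n_ep, nrow(x))), c(3, 2, 1))
      ph[ph <= -pi] <- pi
    }
    structure(list(data = ph, phasor = u, fs = fs, epoch_len = epoch_len,
                   band = band, subject_id = subject_id,
                   n_sources = nrow(x), n_epochs = n_ep, n_samples = spp),
              class = "plv_phase")
  })
  names(out) <- names(bands)
  out
}
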