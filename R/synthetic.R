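#' Generate a clean synthetic single-lead ECG
#'
#' A quasi-periodic P-QRS-T waveform built as a sum of Gaussian deflections
#' per beat, with RR intervals jittered around the nominal heart rate
#' (3% relative SD). Morphology (amplitude mV, offset s relative to the R
#' peak, width s): P (0.12, -0.22, 0.025), Q (-0.12, -0.045, 0.012),
#' R (1.1, 0, 0.022), S (-0.25, 0.035, 0.015), T (0.35, 0.28, 0.06).
#' Deterministic given `seed`.
#'
#' @param duration_s segment duration in seconds (> 0), default 10.
#' @param fs sampling rate in Hz, default 500.
#' @param heart_rate_bpm nominal heart rate, in `[30, 220]`.
#' @param seed integer seed.
#' @param record_id identifier for the resulting record.
#' @return a single-lead [ecg_record] labelled `"acceptable"`.
#' @examples
#' rec <- generate_clean_ecg(10, 500, 60, seed = 1)
#' n_samples(rec)  # 5000
#' @export
generate_clean_ecg <- function(duration_s = 10, fs = 500,
                               heart_rate_bpm = 72, seed = 1,
                               record_id = sprintf("synth%06d", seed)) {
  if (!(duration_s > 0)) stopf("`duration_s` must be positive")
  if (!(fs > 0)) stopf("`fs` must be positive")
  if (!(heart_rate_bpm >= 30 && heart_rate_bpm <= 220))
    stopf("`heart_rate_bpm` must lie in [30, 220]")
  n <- round(duration_s * fs)
  waves <- rbind(  # amp (mV), center offset (s), width (s)
    P = c(0.12, -0.22, 0.025),
    Q = c(-0.12, -0.045, 0.012),
    R = c(1.10, 0.00, 0.022),
    S = c(-0.25, 0.035, 0.015),
    T = c(0.35, 0.28, 0.06))
  x <- with_seed(seed, {
    rr_mean <- 60 / heart_rate_bpm
    nbeat <- ceiling(duration_s / rr_mean) + 3L
    rr <- rr_mean * (1 + 0.03 * rnorm(nbeat))
    centers <- cumsum(rr) - rr[1L] * runif(1L)  # random phase at t = 0
    tt <- (seq_len(n) - 1L) / fs
    sig <- numeric(n)
    for (ctr in centers) {
      for (w in seq_len(nrow(waves))) {
        mu <- ctr + waves[w, 2L]
        sdw <- waves[w, 3L]
        lo <- max(1L, floor((mu - 5 * sdw) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * sdw) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        sig[idx] <- sig[idx] +
          waves[w, 1L] * exp(-((tt[idx] - mu)^2) / (2 * sdw^2))
      }
    }
    sig
  })
  ecg_record(x, fs = fs, lead_names = "I", label = "acceptable",
             record_id = record_id)
}

#' Noise specification
#'
#' @param kind one of `"bw"` (baseline wander), `"em"` (electrode motion),
#'   `"ma"` (muscle artifact), `"gaussian"` (white noise).
#' @param snr_db target signal-to-noise ratio in dB when mixed; default -10
#'   (noise power ten times signal power).
#' @param seed integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(kind = c("bw", "em", "ma", "gaussian"),
                       snr_db = -10, seed = 1) {
  kind <- match.arg(kind)
  if (!is.finite(snr_db)) stopf("`snr_db` must be finite")
  structure(list(kind = kind, snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic contaminant trace
#'
#' Emulates the noise-stress-test contaminant classes: `bw` is a sum of
#' random-phase sinusoids below 0.5 Hz plus a slow random walk; `ma` is white
#' noise band-limited to 5-100 Hz by FFT masking; `em` combines a bw and an
#' ma component with sparse step/spike artifacts; `gaussian` is white normal
#' noise. Each trace is scaled to unit standard deviation (mixing rescales it
#' anyway) and is deterministic given the spec's seed.
#'
#' @param spec a [noise_spec()].
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz.
#' @return numeric vector of `round(duration_s * fs)` amplitudes.
#' @export
generate_noise <- function(spec, duration_s = 10, fs = 500) {
  if (!inherits(spec, "noise_spec")) stopf("`spec` must be a noise_spec")
  n <- round(duration_s * fs)
  x <- with_seed(spec$seed, switch(
    spec$kind,
    bw = noise_bw(n, fs),
    ma = noise_ma(n, fs),
    em = {
      b <- noise_bw(n, fs)
      m <- noise_ma(n, fs)
      0.6 * b + 0.25 * m + 0.6 * noise_steps(n)
    },
    gaussian = rnorm(n),
    stopf("unknown noise kind '%s'", spec$kind)))
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

noise_bw <- function(n, fs) {
  tt <- (seq_len(n) - 1L) / fs
  freqs <- runif(5L, 0.05, 0.45)
  amps <- runif(5L, 0.5, 1)
  phases <- runif(5L, 0, 2 * pi)
  sines <- colSums(amps * sin(outer(freqs, tt, function(f, t) 2 * pi * f * t)
                              + phases))
  walk <- cumsum(rnorm(n)) / sqrt(n)
  sines + 0.5 * walk
}

noise_ma <- function(n, fs) {
  white <- rnorm(n)
  spec <- fft(white)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  spec[freq < 5 | freq > 100] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}

noise_steps <- function(n) {
  k <- rpois(1L, 3L) + 1L
  at <- sort(sample.int(n, k))
  out <- numeric(n)
  for (i in seq_len(k)) {
    jump <- rnorm(1L)
    out[at[i]:n] <- out[at[i]:n] + jump          # electrode step
    spike_end <- min(n, at[i] + rpois(1L, 10L))
    out[at[i]:spike_end] <- out[at[i]:spike_end] + 2 * jump  # transient
  }
  out
}

#' Mix noise into a clean signal at a target SNR
#'
#' Returns `clean + c * noise` with `c` chosen so that
#' `10 * log10(P_clean / P_scaled_noise) == snr_db`, powers being mean
#' squared amplitude over the whole segment. At -10 dB the added noise
#' carries ten times the signal's power.
#'
#' @param clean,noise equal-length numeric vectors with nonzero power.
#' @param snr_db target SNR in dB.
#' @return numeric vector, the corrupted signal.
#' @export
mix_at_snr <- function(clean, noise, snr_db = -10) {
  if (length(clean) != length(noise))
    stopf("`clean` and `noise` must have equal length")
  p_clean <- mean(clean^2)
  p_noise <- mean(noise^2)
  if (p_clean == 0) stopf("`clean` has zero power")
  if (p_noise == 0) stopf("`noise` has zero power")
  if (!is.finite(snr_db)) stopf("`snr_db` must be finite")
  c_scale <- sqrt(p_clean / (p_noise * 10^(snr_db / 10)))
  clean + c_scale * noise
}

#' Measured SNR of an additive component
#'
#' `10 * log10(mean(clean^2) / mean(added^2))`, the segment-level definition
#' used by [mix_at_snr()].
#'
#' @param clean the uncorrupted signal.
#' @param added the (scaled) noise that was added, i.e. `corrupted - clean`.
#' @return SNR in dB.
#' @export
measured_snr_db <- function(clean, added) {
  10 * log10(mean(clean^2) / mean(added^2))
}

#' Apportion noise kinds across records
#'
#' Integerizes counts proportional to `weights` by the largest-remainder
#' rule so they sum exactly to `n_signals`. With the default 2:2:2:1
#' weighting, 7882 signals split as bw/em/ma 2252 each and gaussian 1126.
#'
#' @param n_signals total number of records to corrupt (>= 0).
#' @param weights named nonnegative weights per noise kind, at least one
#'   positive.
#' @return named integer vector of counts summing to `n_signals`.
#' @examples
#' plan_noise_allocation(7882, c(bw = 2, em = 2, ma = 2, gaussian = 1))
#' @export
plan_noise_allocation <- function(n_signals,
                                  weights = c(bw = 2, em = 2, ma = 2,
                                              gaussian = 1)) {
  if (n_signals < 0) stopf("`n_signals` must be nonnegative")
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stopf("`weights` must be named by noise kind")
  if (any(weights < 0) || all(weights == 0))
    stopf("`weights` must be nonnegative with at least one positive entry")
  quota <- n_signals * weights / sum(weights)
  base <- floor(quota)
  rem <- n_signals - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  out <- as.integer(base)
  names(out) <- names(weights)
  out
}

#' Build a balanced acceptable/unacceptable dataset
#'
#' Mirrors the dataset construction pipeline: unacceptable records with an
#' empty (flat) lead are removed; a planned subset of the acceptable pool is
#' corrupted -- each chosen record gets exactly one noise kind mixed in at
#' `snr_db` -- and the corrupted copy is relabelled unacceptable. Originals
#' remain in the acceptable class; corrupted copies get the noise kind as an
#' id suffix, so no id ever carries two noise kinds.
#'
#' @param clean_records list of acceptable single-lead [ecg_record]s.
#' @param unacceptable_records list of unacceptable [ecg_record]s (screened
#'   for empty leads before inclusion).
#' @param n_corrupt how many clean records to corrupt; the default
#'   `length(clean_records) - length(unacceptable_records)` mirrors the
#'   reference corpus proportions. Must not exceed the clean pool.
#' @param allocation_weights noise-kind weights for [plan_noise_allocation()].
#' @param snr_db mixing SNR in dB, default -10.
#' @param seed run seed; drives the choice of corrupted subset and all noise.
#' @return list with `manifest` (data.frame: record_id, source, noise_kind,
#'   label), `records` (all emitted records), `counts_by_class`, and
#'   `n_removed_empty`.
#' @export
build_dataset <- function(clean_records, unacceptable_records,
                          n_corrupt = NULL,
                          allocation_weights = c(bw = 2, em = 2, ma = 2,
                                                 gaussian = 1),
                          snr_db = -10, seed = 1) {
  stopifnot(all(vapply(clean_records, is_ecg_record, logical(1L))),
            all(vapply(unacceptable_records, is_ecg_record, logical(1L))))
  n_corrupt <- n_corrupt %||%
    max(0L, length(clean_records) - length(unacceptable_records))
  if (n_corrupt > length(clean_records))
    stopf("allocation of %d exceeds the clean pool of %d",
          n_corrupt, length(clean_records))

  empty <- vapply(unacceptable_records,
                  function(r) any(detect_empty_leads(r)), logical(1L))
  kept_unacc <- unacceptable_records[!empty]

  alloc <- plan_noise_allocation(n_corrupt, allocation_weights)
  kinds <- rep(names(alloc), times = alloc)
  chosen <- with_seed(derive_seed(seed, 1L),
                      sample.int(length(clean_records), n_corrupt))
  corrupted <- vector("list", n_corrupt)
  for (i in seq_len(n_corrupt)) {
    src <- clean_records[[chosen[i]]]
    mixed <- vapply(seq_len(n_leads(src)), function(L) {
      spec <- noise_spec(kinds[i], snr_db = snr_db,
                         seed = derive_seed(seed, 100L + 16L * i + L))
      nz <- generate_noise(spec, duration_s = duration_seconds(src),
                           fs = src$fs)
      mix_at_snr(as.numeric(src$samples[, L]), nz, snr_db)
    }, numeric(n_samples(src)))
    corrupted[[i]] <- ecg_record(mixed, fs = src$fs,
                                 lead_names = src$lead_names,
                                 label = "unacceptable",
                                 record_id = paste0(src$record_id, "_",
                                                    kinds[i]))
  }

  records <- c(clean_records, kept_unacc, corrupted)
  manifest <- data.frame(
    record_id = vapply(records, `[[`, character(1L), "record_id"),
    source = c(rep("clean", length(clean_records) + length(kept_unacc)),
               rep("corrupted", n_corrupt)),
    noise_kind = c(rep(NA_character_, length(clean_records) +
                         length(kept_unacc)), kinds),
    label = c(rep("acceptable", length(clean_records)),
              rep("unacceptable", length(kept_unacc)),
              rep("unacceptable", n_corrupt)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$record_id))
    stopf("duplicate record ids in dataset manifest")
  list(manifest = manifest, records = records,
       counts_by_class = table(manifest$label),
       n_removed_empty = sum(empty))
}
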