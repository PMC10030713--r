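test_that("clean ECG generator is deterministic with plausible morphology", {
  rec <- generate_clean_ecg(10, 500, 60, seed = 21)
  expect_identical(n_samples(rec), 5000L)
  expect_identical(rec$samples,
                   generate_clean_ecg(10, 500, 60, seed = 21)$samples)
  expect_false(identical(rec$samples,
                         generate_clean_ecg(10, 500, 60, seed = 22)$samples))
  # threshold peak detection: ~10 R peaks in 10 s at 60 bpm
  x <- rec$samples[, 1L]
  thr <- 0.6 * max(x)
  peaks <- which(x[2:4999] > thr & x[2:4999] >= x[1:4998] &
                   x[2:4999] >= x[3:5000]) + 1L
  n_r <- sum(diff(c(-1000, peaks)) > 100)  # collapse adjacent samples
  expect_true(n_r %in% 9:11)
  expect_error(generate_clean_ecg(10, 500, 20, seed = 1), "heart_rate")
  expect_error(generate_clean_ecg(-1, 500, 60, seed = 1), "duration")
})

test_that("noise generators match their spectral contracts", {
  for (kind in c("bw", "em", "ma", "gaussian")) {
    s <- noise_spec(kind, seed = 9)
    x <- generate_noise(s, 10, 500)
    expect_length(x, 5000L)
    expect_identical(x, generate_noise(s, 10, 500))
  }
  expect_error(noise_spec("pink"), "arg")
  # bw: >= 90% of spectral power below 1 Hz
  x <- generate_noise(noise_spec("bw", seed = 4), 10, 500)
  p <- Mod(fft(x))^2
  freq <- (seq_along(x) - 1) * 500 / length(x)
  freq <- pmin(freq, 500 - freq)
  expect_gte(sum(p[freq < 1]) / sum(p), 0.9)
  # gaussian: sample mean within 3 sd/sqrt(n) of zero
  g <- generate_noise(noise_spec("gaussian", seed = 10), 10, 500)
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)))
  # ma: band-limited, little power below 5 Hz
  m <- generate_noise(noise_spec("ma", seed = 5), 10, 500)
  pm <- Mod(fft(m))^2
  expect_lt(sum(pm[freq < 4.5]) / sum(pm), 0.05)
})

test_that("mix_at_snr realizes the requested SNR exactly", {
  clean <- generate_clean_ecg(10, 500, 72, seed = 2)$samples[, 1L]
  for (seed in 1:8) {
    for (target in c(-10, 0, 6.2)) {
      nz <- generate_noise(noise_spec("em", seed = seed), 10, 500)
      mixed <- mix_at_snr(clean, nz, target)
      expect_equal(measured_snr_db(clean, mixed - clean), target,
                   tolerance = 1e-9)
    }
  }
  # 0 dB: scaled noise power equals clean power
  nz <- generate_noise(noise_spec("gaussian", seed = 3), 10, 500)
  at0 <- mix_at_snr(clean, nz, 0)
  expect_equal(mean((at0 - clean)^2), mean(clean^2), tolerance = 1e-9)
  expect_error(mix_at_snr(clean, numeric(5000), -10), "zero power")
  expect_error(mix_at_snr(numeric(5000), nz, -10), "zero power")
  expect_error(mix_at_snr(clean, nz[-1], -10), "equal length")
})

test_that("noise allocation follows the largest-remainder rule", {
  expect_identical(plan_noise_allocation(7882),
                   c(bw = 2252L, em = 2252L, ma = 2252L, gaussian = 1126L))
  expect_identical(unname(plan_noise_allocation(0)), rep(0L, 4L))
  a7 <- plan_noise_allocation(7, c(a = 1, b = 1, c = 1, d = 1))
  expect_identical(sum(a7), 7L)
  expect_identical(sort(unname(a7)), c(1L, 2L, 2L, 2L))
  expect_error(plan_noise_allocation(5, c(a = 0, b = 0)), "positive")
  # property: sums match and deviation from proportionality < 1
  set.seed(77)
  for (i in 1:25) {
    n <- sample.int(5000, 1)
    w <- runif(4)
    names(w) <- letters[1:4]
    a <- plan_noise_allocation(n, w)
    expect_identical(sum(a), as.integer(n))
    expect_true(all(abs(a - n * w / sum(w)) < 1))
  }
})

test_that("build_dataset screens empty leads and conserves records", {
  clean <- lapply(1:20, function(i)
    generate_clean_ecg(2, 100, 70, seed = 30 + i,
                       record_id = sprintf("c%02d", i)))
  bad_flat <- lapply(1:3, function(i)
    ecg_record(rep(i * 0.1, 200), fs = 100, label = "unacceptable",
               record_id = sprintf("flat%d", i)))
  bad_noisy <- lapply(1:4, function(i)
    ecg_record(generate_noise(noise_spec("em", seed = 40 + i), 2, 100),
               fs = 100, label = "unacceptable",
               record_id = sprintf("noisy%d", i)))
  ds <- build_dataset(clean, c(bad_flat, bad_noisy), seed = 5)
  expect_identical(ds$n_removed_empty, 3L)
  # default corruption count = clean pool - unacceptable input
  expect_identical(sum(ds$manifest$source == "corrupted"), 13L)
  expect_identical(unname(ds$counts_by_class["acceptable"]), 20L)
  expect_identical(unname(ds$counts_by_class["unacceptable"]), 4L + 13L)
  # conservation: inputs + corrupted copies = manifest + removals
  expect_identical(20L + 7L + 13L, nrow(ds$manifest) + ds$n_removed_empty)
  # one noise kind per id, ids unique
  expect_identical(anyDuplicated(ds$manifest$record_id), 0L)
  kinds <- ds$manifest$noise_kind[!is.na(ds$manifest$noise_kind)]
  expect_identical(length(kinds), 13L)
  expect_true(all(kinds %in% c("bw", "em", "ma", "gaussian")))
  expect_error(build_dataset(clean[1:3], list(), n_corrupt = 10),
               "exceeds")
  # corrupted records measure the default -10 dB against their source
  src_id <- sub("_(bw|em|ma|gaussian)$", "",
                ds$manifest$record_id[ds$manifest$source == "corrupted"][1L])
  src <- clean[[match(src_id, vapply(clean, `[[`, "", "record_id"))]]
  cor <- ds$records[[which(ds$manifest$source == "corrupted")[1L]]]
  expect_equal(measured_snr_db(src$samples[, 1L],
                               cor$samples[, 1L] - src$samples[, 1L]),
               -10, tolerance = 1e-9)
})
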