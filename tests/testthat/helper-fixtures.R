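# Fixtures built in code at test time.

unit_square <- function() matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2,
                                 byrow = TRUE)

random_cloud <- function(n, d = 2) matrix(stats::rnorm(n * d), ncol = d)

twelve_lead_record <- function(n = 400, fs = 100) {
  base <- sin(seq(0, 8 * pi, length.out = n))
  m <- outer(base, seq(0.5, 1.6, length.out = 12)) +
    matrix(stats::rnorm(n * 12, sd = 0.01), n, 12)
  ecg_record(m, fs = fs, lead_names = sprintf("L%02d", 1:12),
             label = "acceptable", record_id = "fix12")
}

# WFDB format-16 fixture written at test time; returns the header path.
write_wfdb_fixture <- function(dir, name = "rec01", fs = 500, nsamp = 500,
                               gain = 200, baseline = 0) {
  t <- seq_len(nsamp) / fs
  mv <- cbind(sin(2 * pi * 1.2 * t), cos(2 * pi * 0.8 * t))
  adc <- round(mv * gain + baseline)
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(c(sprintf("%s 2 %g %d", name, fs, nsamp),
               sprintf("%s.dat 16 %g(%g)/mV 16 0 0 0 0 I", name, gain,
                       baseline),
               sprintf("%s.dat 16 %g(%g)/mV 16 0 0 0 0 II", name, gain,
                       baseline)),
             hea)
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  close(con)
  list(hea = hea, mv_quantized = sweep(adc, 2, baseline, `-`) / gain, fs = fs)
}

# Two visually distinct diagram families for classifier tests: "clean"-like
# sparse diagrams vs "noisy"-like dense wide-range diagrams.
toy_image_set <- function(n_per_class, side = 96L, seed = 1) {
  style <- render_style(side_px = side)
  imgs <- list(); labels <- character(0)
  for (i in seq_len(n_per_class)) {
    set.seed(seed + i)
    d1 <- persistence_diagram(rep(0L, 6L), birth = runif(6, -1, -0.6),
                              death = runif(6, -0.5, 0), source = "sls")
    set.seed(seed + 1000 + i)
    d2 <- persistence_diagram(rep(0L, 40L), birth = runif(40, -1, 0.5),
                              death = runif(40, 0.5, 1), source = "sls")
    imgs <- c(imgs, list(render_diagram(d1, style, value_range = c(-1, 1)),
                         render_diagram(d2, style, value_range = c(-1, 1))))
    labels <- c(labels, "acceptable", "unacceptable")
  }
  list(images = imgs, labels = labels)
}
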