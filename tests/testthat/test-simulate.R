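test_that("generation is bit-reproducible and exactly class-balanced", {
  sp <- synth_preset("p300_like", n_epochs_per_class = 10, seed = 3)
  a <- synth_generate(sp)
  b <- synth_generate(sp)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  expect_equal(as.integer(table(a$labels)), c(10L, 10L))
  expect_identical(dim(a$data), c(20L, sp$n_channels, sp$n_samples))
  expect_equal(a$provenance$seed, 3L)
})

test_that("the class-conditional ERP amplitude is recovered from the epoch means", {
  sp <- synth_spec(n_epochs_per_class = 100, seed = 21,
                   background = list(exponent = 1, amplitude = 10),
                   erp = list(latency_ms = 300, width_ms = 45, amplitude = 8,
                              sign = 1, jitter_ms = 0, channels = 4:8),
                   oscillation = list(amplitude = 0),
                   artifacts = list(blink_rate = 0, line_amplitude = 0))
  es <- synth_generate(sp)
  lat_sample <- round(300 / 1000 * sp$sampling_rate) + 1L
  ch <- 7L
  x1 <- es$data[es$labels == 1, ch, lat_sample]
  x0 <- es$data[es$labels == 0, ch, lat_sample]
  diff <- mean(x1) - mean(x0)
  se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
  expect_lt(abs(diff - 8), 3 * se)
})

test_that("the oscillation-only signal peaks at the configured frequency bin", {
  sp <- synth_spec(n_epochs_per_class = 20, seed = 4, n_samples = 256,
                   background = list(amplitude = 0),
                   erp = list(amplitude = 0, latency_ms = 300, width_ms = 40),
                   oscillation = list(freq_hz = 10, amplitude = 5,
                                      burst_ms = 1000, onset_ms = 200),
                   artifacts = list(blink_rate = 0, line_amplitude = 0),
                   class_effect = "oscillation")
  es <- synth_generate(sp)
  x <- es$data[es$labels == 1, 1, ]
  pg <- rowMeans(apply(x, 1, function(tr) Mod(fft(tr))[2:128]^2))
  freqs <- (1:127) * sp$sampling_rate / 256
  expect_lt(abs(freqs[which.max(pg)] - 10), sp$sampling_rate / 256 + 1e-9)
})

test_that("the background log-periodogram slope matches the configured exponent", {
  for (expo in c(1, 1.5)) {
    sp <- synth_spec(n_epochs_per_class = 50, seed = 8, n_samples = 256,
                     background = list(exponent = expo, amplitude = 10),
                     erp = list(amplitude = 0, latency_ms = 300, width_ms = 40),
                     oscillation = list(amplitude = 0),
                     artifacts = list(blink_rate = 0, line_amplitude = 0))
    es <- synth_generate(sp)
    nf <- 128L
    freqs <- (1:(nf - 1)) * sp$sampling_rate / 256
    keep <- freqs >= 2 & freqs <= 40
    pg <- rowMeans(apply(es$data[, 1, ], 1, function(tr) Mod(fft(tr))[2:nf]^2))
    slope <- coef(lm(log(pg[keep]) ~ log(freqs[keep])))[2]
    expect_lt(abs(slope + expo), 0.2)
  }
})

test_that("components are additive: one amplitude at a time reproduces that component", {
  base <- list(n_epochs_per_class = 3, seed = 12, n_channels = 4,
               background = list(amplitude = 0),
               erp = list(amplitude = 0, latency_ms = 300, width_ms = 40,
                          sign = 1, jitter_ms = 0, channels = 1:2),
               oscillation = list(amplitude = 0),
               artifacts = list(blink_rate = 0, line_amplitude = 0))
  zero <- synth_generate(do.call(synth_spec, base))
  expect_equal(max(abs(zero$data)), 0)
  only_line <- base
  only_line$artifacts <- list(blink_rate = 0, line_amplitude = 2,
                              line_freq_hz = 50)
  es <- synth_generate(do.call(synth_spec, only_line))
  # pure sinusoid on every channel: amplitude 2 up to grid sampling, channels equal
  expect_equal(max(abs(es$data)), 2, tolerance = 0.01)
  expect_equal(es$data[1, 1, ], es$data[1, 4, ])
  only_erp <- base
  only_erp$erp$amplitude <- 5
  es2 <- synth_generate(do.call(synth_spec, only_erp))
  expect_equal(max(abs(es2$data[es2$labels == 0, , ])), 0)   # effect on class 1 only
  expect_equal(max(es2$data[es2$labels == 1, 1, ]), 5, tolerance = 0.01)
  expect_equal(max(abs(es2$data[, 3:4, ])), 0)               # target channels only
})

test_that("presets encode the documented ERP phenomenology", {
  p300 <- synth_preset("p300_like")
  expect_equal(p300$erp$latency_ms, 300)
  expect_gt(p300$erp$sign, 0)
  confl <- synth_preset("conflict_like")
  expect_lt(confl$erp$sign, 0)
  expect_true(confl$erp$latency_ms >= 150 && confl$erp$latency_ms <= 250)
  mi <- synth_preset("mi_like")
  expect_true(mi$oscillation$freq_hz >= 8 && mi$oscillation$freq_hz <= 13)
  expect_identical(mi$class_effect, "oscillation")
  mrcp <- synth_preset("mrcp_like")
  expect_equal(mrcp$n_classes, 4L)
  expect_lt(mrcp$erp$sign, 0)
  expect_error(synth_preset("banana"), "arg")
})

test_that("invalid generator specifications fail before any sampling", {
  expect_error(synth_spec(erp = list(latency_ms = 900, width_ms = 80)),
               "exceeds epoch length")
  expect_error(synth_spec(oscillation = list(freq_hz = 80, amplitude = 1)),
               "Nyquist")
  expect_error(synth_spec(artifacts = list(blink_rate = -1)), ">= 0")
  expect_error(synth_spec(n_epochs_per_class = 1), "at least 2")
})

test_that("the epoch container round-trips losslessly through HDF5 + sidecar", {
  sp <- synth_preset("conflict_like", n_epochs_per_class = 5, seed = 9)
  es <- synth_generate(sp)
  path <- tempfile(fileext = ".h5")
  save_epochs(es, path)
  es2 <- load_epochs(path)
  expect_equal(es2$data, es$data)
  expect_identical(es2$labels, es$labels)
  expect_equal(es2$sampling_rate, es$sampling_rate)
  expect_identical(es2$channel_names, es$channel_names)
  expect_equal(es2$provenance$seed, 9)   # provenance carries the generator seed
})

test_that("corrupt or incomplete containers produce descriptive errors, never partial sets", {
  sp <- synth_preset("p300_like", n_epochs_per_class = 3, seed = 1)
  es <- synth_generate(sp)
  path <- tempfile(fileext = ".h5")
  save_epochs(es, path)
  # truncated HDF5 payload
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:200], path)
  expect_error(load_epochs(path), "corrupt|unreadable")
  # missing sidecar
  path2 <- tempfile(fileext = ".h5")
  save_epochs(es, path2)
  unlink(enkit:::sidecar_path(path2))
  expect_error(load_epochs(path2), "sidecar")
  # missing metadata key
  path3 <- tempfile(fileext = ".h5")
  save_epochs(es, path3)
  meta <- jsonlite::read_json(enkit:::sidecar_path(path3))
  meta$sampling_rate <- NULL
  jsonlite::write_json(meta, enkit:::sidecar_path(path3), auto_unbox = TRUE)
  expect_error(load_epochs(path3), "sampling_rate")
  expect_error(load_epochs(tempfile(fileext = ".h5")), "not found")
})
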