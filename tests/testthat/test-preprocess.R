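make_rec <- function(x, fs = 25000, stim = numeric(0)) {
  raw_recording(matrix(x, 1, dimnames = list("C-01", NULL)), fs,
                electrode_map("C-01", "C"), stimulation_times = stim)
}

test_that("band-pass passes 1 kHz and strongly attenuates 50 Hz and 10 kHz", {
  fs <- 25000
  tt <- (0:(2 * fs - 1)) / fs
  gain <- function(f) {
    rec <- make_rec(sin(2 * pi * f * tt))
    y <- bandpass_notch_filter(rec)$samples[1, ]
    core <- seq(fs / 2, 3 * fs / 2)  # avoid edges
    max(abs(y[core]))
  }
  expect_gt(gain(1000), 0.9)
  expect_lt(gain(50), 1e-4)    # below band edge, plus the notch
  expect_lt(gain(10), 1e-6)
  expect_lt(gain(10000), 0.05)
})

test_that("the mains notch alone removes a 50 Hz tone but spares 1 kHz", {
  fs <- 25000
  tt <- (0:(2 * fs - 1)) / fs
  nt <- meacircuit:::design_notch(50, fs, 30)
  core <- seq(fs / 2, 3 * fs / 2)
  y50 <- meacircuit:::filtfilt_reflect(nt$b, nt$a, sin(2 * pi * 50 * tt))
  y1k <- meacircuit:::filtfilt_reflect(nt$b, nt$a, sin(2 * pi * 1000 * tt))
  expect_lt(max(abs(y50[core])), 0.02)
  expect_gt(max(abs(y1k[core])), 0.99)
})

test_that("filtering is zero-phase: passband tone keeps its phase", {
  fs <- 25000
  tt <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 1000 * tt)
  y <- bandpass_notch_filter(make_rec(x))$samples[1, ]
  core <- seq(fs / 4, 3 * fs / 4)
  # a phase shift would move the best alignment off zero lag
  lags <- -5:5
  cors <- vapply(lags, function(l)
    sum(x[core] * y[core + l]), numeric(1))
  expect_equal(lags[which.max(cors)], 0)
})

test_that("filtering a symmetric pulse keeps its peak sample (no group delay)", {
  fs <- 25000
  x <- numeric(fs / 2)
  peak <- 6000
  x[peak + (-25:25)] <- exp(-(-25:25)^2 / 50)
  y <- bandpass_notch_filter(make_rec(x))$samples[1, ]
  expect_equal(which.max(y), peak)
})

test_that("high_cut at or above Nyquist is rejected", {
  rec <- make_rec(rnorm(1000), fs = 5000)
  expect_error(bandpass_notch_filter(rec), "Nyquist")
})

test_that("iir_filter matches the reference difference equation", {
  set.seed(9)
  b <- c(0.2, -0.1, 0.05); a <- c(1, -0.4, 0.1)
  x <- rnorm(300)
  y <- meacircuit:::iir_filter(b, a, x)
  ref <- numeric(300)
  for (i in seq_along(x)) {
    ref[i] <- sum(b * c(x[i], if (i > 1) x[i - 1] else 0,
                        if (i > 2) x[i - 2] else 0)) -
      sum(a[-1] * c(if (i > 1) ref[i - 1] else 0,
                    if (i > 2) ref[i - 2] else 0))
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("SALPA removes a cubic artifact and leaves the rest untouched", {
  fs <- 25000
  n <- fs  # 1 s
  tt <- (0:(n - 1)) / fs
  stim <- 0.2
  u <- tt - stim
  sel <- u >= 0 & u < 0.3
  x <- numeric(n)
  x[sel] <- 300 - 800 * u[sel] + 500 * u[sel]^2 + 1200 * u[sel]^3
  rec <- make_rec(x, stim = stim)
  out <- salpa_subtract(rec, config = analysis_config(), noise_band = 1e-3)
  expect_lt(max(abs(out$samples[1, sel])) / max(abs(x[sel])), 1e-6)
  expect_identical(out$samples[1, !sel], x[!sel])
})

test_that("SALPA stops subtracting once the artifact has decayed", {
  fs <- 25000
  n <- fs
  tt <- (0:(n - 1)) / fs
  stim <- 0.1
  u <- tt - stim
  # artifact decays to zero within 50 ms; a later test pulse must survive
  x <- 200 * exp(-pmax(u, 0) / 0.01) * (u >= 0)
  pulse <- round((stim + 0.2) * fs):round((stim + 0.21) * fs)
  x[pulse] <- x[pulse] + 5
  rec <- make_rec(x, stim = stim)
  out <- salpa_subtract(rec, config = analysis_config(), noise_band = 1)
  expect_equal(out$samples[1, pulse], x[pulse])
})

test_that("pegged samples are interpolated before the SALPA fit", {
  fs <- 25000
  n <- fs
  tt <- (0:(n - 1)) / fs
  stim <- 0.1
  u <- tt - stim
  sel <- u >= 0 & u < 0.3
  x <- numeric(n)
  x[sel] <- 400 - 1000 * u[sel]
  x[x > 390] <- 400  # rail
  rec <- make_rec(x, stim = stim)
  out <- salpa_subtract(rec, config = analysis_config(), noise_band = 1e-3,
                        pegged_limit = 395)
  # away from the railed stretch, the linear artifact is removed
  late <- u >= 0.1 & u < 0.29
  expect_lt(max(abs(out$samples[1, late])), 1e-6)
})

test_that("blanking drops spikes in the half-open window and records the mask", {
  m <- tiny_map(1)
  tab <- spike_table(
    data.frame(electrode_id = "C-01",
               spike_time = c(0.5, 1.0, 1.005, 1.0149, 1.015, 2)),
    duration = 3, electrode_map = m,
    metadata = list(stimulation_times = 1))
  out <- blank_after_stimulus(tab, 1, blank = 0.015)
  expect_equal(out$spikes$spike_time, c(0.5, 1.015, 2))
  expect_equal(out$masked, data.frame(start = 1, end = 1.015))
  expect_equal(meacircuit:::unmasked_duration(out), 3 - 0.015)
})

test_that("blanking a raw recording zeroes the blanked samples", {
  fs <- 1000
  rec <- make_rec(rep(1, 2 * fs), fs = fs, stim = 0.5)
  out <- blank_after_stimulus(rec, blank = 0.1)
  expect_true(all(out$samples[1, 501:600] == 0))
  expect_true(all(out$samples[1, 701:2000] == 1))
  expect_equal(attr(out, "masked"), data.frame(start = 0.5, end = 0.6))
})
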