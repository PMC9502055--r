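test_that("templates are periodic with the planted range and morphology", {
  cases <- list(list(gait = "walk", rom = 58, ratio = 1.0),
                list(gait = "walk", rom = 58, ratio = 0.9),
                list(gait = "trot", rom = 80, ratio = 0.9),
                list(gait = "trot", rom = 89, ratio = 1.0))
  for (cs in cases) {
    wf <- make_fja_waveform(cs$gait, cs$rom, cs$ratio)
    # value and first derivative match across the phase boundary
    for (d in c(0, 1e-4, 0.01)) {
      expect_lt(abs(wf$fn(1 + d) - wf$fn(d)), 1e-10)
      expect_lt(abs(wf$deriv(1 + d) - wf$deriv(d)), 1e-8)
    }
    # exact continuous range equals the planted ROM
    expect_equal(waveform_range(wf), cs$rom, tolerance = 1e-9)
    # flexion double peak in both gaits
    expect_identical(count_flexion_peaks(wf), 2L)
  }
})

test_that("walk shows two extension peaks, trot a single one", {
  walk <- make_fja_waveform("walk", 58, 1.0)
  expect_identical(count_flexion_peaks(walk), 2L)
  expect_identical(count_extension_peaks(walk), 2L)
  # the walk template alternates flexion and extension, so even the strict
  # circular extremum counts are 2 and 2
  expect_identical(unname(count_strict_extrema(walk)), c(2L, 2L))

  trot <- make_fja_waveform("trot", 80, 0.9)
  expect_identical(count_extension_peaks(trot), 1L)
  # the inter-peak dip of the trot double flexion peak stays positive: it is
  # a strict minimum but not an extension peak
  expect_identical(unname(count_strict_extrema(trot))[2], 2L)
})

test_that("flexion peak ratio controls the relative peak heights", {
  wf <- make_fja_waveform("trot", 80, 0.7)
  p <- seq(0, 1, length.out = 4096)
  v <- wf$fn(p)
  pk <- sort(v[c(FALSE, diff(sign(diff(v))) == -2)], decreasing = TRUE)
  pk <- pk[pk > 0]
  expect_identical(length(pk), 2L)
  expect_lt(pk[2] / pk[1], 0.85)
  sym <- make_fja_waveform("trot", 80, 1.0)
  vs <- sym$fn(p)
  pks <- sort(vs[c(FALSE, diff(sign(diff(vs))) == -2)], decreasing = TRUE)
  pks <- pks[pks > 0]
  expect_equal(pks[1], pks[2], tolerance = 1e-3)  # grid-limited comparison
})

test_that("invalid template arguments are rejected", {
  expect_error(make_fja_waveform("gallop", 60), "unknown gait")
  expect_error(make_fja_waveform("walk", -3), "rom_deg")
  expect_error(make_fja_waveform("walk", 60, 0), "flexion_peak_ratio")
  expect_error(make_fja_waveform("walk", 60, 1.2), "flexion_peak_ratio")
})
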