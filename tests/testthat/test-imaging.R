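test_that("generator places the requested signal split and records truth", {
  img <- simulate_comet_image(0.4, total_signal = 5e4)
  expect_s3_class(img, "comet_image")
  expect_equal(sum(img$pixels), 5e4, tolerance = 1e-8)
  expect_equal(img$truth_tail_fraction, 0.4)
  expect_true(all(img$pixels >= 0))
  # all head signal left of/at the centre column plus the symmetric right lobe
  expect_error(simulate_comet_image(1.2), "tail_fraction")
  expect_error(simulate_comet_image(0.5, tail_length = 2000),
               "fit inside the frame")
})

test_that("a pure-head comet scores near zero and a blank frame is unscorable", {
  s <- score_comet(simulate_comet_image(0))
  expect_lt(abs(s$tail_intensity), 1)
  expect_error(score_comet(simulate_comet_image(0, total_signal = 0)),
               "unscorable")
})

test_that("noise-free recovery over the tail-fraction grid is within 2 points", {
  tf <- seq(0.1, 0.9, by = 0.1)
  err <- sapply(tf, function(f)
    score_comet(simulate_comet_image(f))$tail_intensity - 100 * f)
  expect_lt(mean(abs(err)), 2)
  expect_lt(max(abs(err)), 2)
})

test_that("the gaussian-fit head policy recovers truth comparably", {
  for (f in c(0.2, 0.6)) {
    s <- score_comet(simulate_comet_image(f), head_policy = "fit-gaussian")
    expect_equal(s$tail_intensity, 100 * f, tolerance = 2 / (100 * f))
  }
})

test_that("poisson-noise recovery at high signal is within 4 points", {
  tf <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  err <- sapply(tf, function(f)
    score_comet(simulate_comet_image(f, noise_model = "poisson",
                                     total_signal = 1e5,
                                     seed = round(100 * f)))$tail_intensity -
      100 * f)
  expect_lt(max(abs(err)), 4)
})

test_that("head and tail percentages always sum to 100", {
  for (f in c(0, 0.25, 0.5, 0.75)) {
    s <- score_comet(simulate_comet_image(f, noise_model = "poisson",
                                          seed = 1 + round(4 * f)))
    expect_identical(s$head_pct + s$tail_intensity, 100)
  }
})

test_that("scoring is deterministic and background-offset invariant", {
  img <- simulate_comet_image(0.4)
  s1 <- score_comet(img); s2 <- score_comet(img)
  expect_identical(s1$tail_intensity, s2$tail_intensity)
  img2 <- img
  img2$pixels <- img$pixels + 0.1 * max(img$pixels)
  s3 <- score_comet(img2)
  expect_lt(abs(s3$tail_intensity - s1$tail_intensity), 1)
})

test_that("comet images round-trip through 16-bit TIFF with truth sidecar", {
  d <- tempfile(); dir.create(d)
  img <- simulate_comet_image(0.35, total_signal = 2e4)
  path <- file.path(d, "comet_01.tif")
  write_comet_tiff(img, path)
  expect_true(file.exists(paste0(path, ".truth")))
  back <- read_comet_tiff(path)
  expect_equal(back$truth_tail_fraction, 0.35)
  # 16-bit quantisation: scores agree closely
  expect_equal(score_comet(back)$tail_intensity,
               score_comet(img)$tail_intensity, tolerance = 0.01)
  unlink(d, recursive = TRUE)
})

test_that("batch scoring emits one validated row per scorable image", {
  d <- tempfile(); dir.create(d)
  for (i in 1:3)
    write_comet_tiff(simulate_comet_image(0.2 * i, total_signal = 2e4),
                     file.path(d, sprintf("c%02d.tif", i)))
  tbl <- score_comet_dir(d)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$tail_intensity, tbl$truth_tail_pct, tolerance = 0.1)
  unlink(d, recursive = TRUE)
})
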