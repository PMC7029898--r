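test_that("mean brightness is the plain grid mean", {
  expect_equal(mean_brightness(matrix(77, 6, 9)), 77)
  expect_equal(mean_brightness(matrix(c(100, 120, 110, 130), 2, 2)), 115)
  # rows all at/below the centre are untouched by rescale: mean exactly 109
  expect_equal(mean_brightness(rescale_rows(normalize_rows(matrix(109, 4, 5)))), 109)
})

test_that("roughness is 1 on flat profiles and matches hand evaluation", {
  expect_equal(roughness(matrix(109, 200, 500), n = 100)$r_bar, 1)
  expect_equal(roughness(matrix(5, 3, 47), n = 10)$r_bar, 1)

  r <- roughness(matrix(c(0, 146), nrow = 1), n = 1)
  expect_equal(r$s, 2)
  expect_equal(r$n_actual, 1)
  expect_equal(r$r_bar, sqrt(146^2 + 2^2) / 2)

  expect_error(roughness(matrix(0, 2, 5), n = 6), "1 <= n")
})

test_that("roughness agrees with the brute-force polyline oracle", {
  set.seed(9)
  for (i in 1:300) {
    px <- rand_roi()
    n <- sample(seq_len(ncol(px)), 1)
    expect_equal(roughness(px, n)$r_bar, roughness_oracle(px, n), tolerance = 1e-9)
    expect_equal(roughness(px, n, rule = "exact-n")$r_bar,
                 roughness_oracle(px, n, rule = "exact-n"), tolerance = 1e-9)
  }
})

test_that("roughness responds monotonically to fluctuation amplitude", {
  set.seed(10)
  base <- matrix(runif(200, -1, 1), 5, 40)
  r <- sapply(c(5, 20, 60), function(amp) {
    roughness(pmin(pmax(109 + amp * base, 0), 255), n = 10)$r_bar
  })
  expect_true(all(diff(r) > 0))
  # doubling every brightness difference never decreases r_bar
  expect_gte(roughness(109 + 2 * 30 * base, n = 10)$r_bar,
             roughness(109 + 30 * base, n = 10)$r_bar)
})

test_that("histograms conserve counts and quantize round-half-up", {
  h <- build_histogram(matrix(109, 10, 10))
  expect_equal(h$counts[110], 100)
  expect_equal(h$H, 100)
  expect_equal(h$I_H, 109)
  expect_equal(sum(h$counts), 100)

  two <- matrix(c(rep(108, 60), rep(200, 40)), 10, 10)
  h2 <- build_histogram(two)
  expect_equal(h2$counts[c(109, 201)], c(60, 40))
  expect_equal(h2$I_H, 108)

  # .5 rounds up
  h3 <- build_histogram(matrix(c(108.5, 108.49), 1, 2))
  expect_equal(h3$counts[c(109, 110)], c(1, 1))

  set.seed(11)
  px <- rand_roi(8)
  expect_equal(sum(build_histogram(px)$counts), length(px))
})

test_that("apex redefinition follows the FWHM-centroid rule", {
  tri <- hist_from_counts(triangle_counts(120))
  a <- apex_brightness(tri)
  expect_equal(a$I_Hbar, 120)
  expect_equal(a$I_h, 120)

  # centroid within 3 units of the mode: keep the mode
  counts <- numeric(256)
  counts[110 + 1] <- 100
  counts[c(108, 109, 111, 112, 113, 114) + 1] <- c(60, 80, 80, 70, 60, 55)
  h <- hist_from_counts(counts)
  a2 <- apex_brightness(h)
  expect_equal(h$I_H, 110)
  expect_lte(abs(a2$I_Hbar - 110), 3)
  expect_equal(a2$I_h, 110)

  # secondary shoulder contiguous with the peak (counts stay above half
  # height) widens the FWHM window and drags the centroid: apex redefined
  counts <- numeric(256)
  counts[109 + 1] <- 100
  counts[c(107, 108, 110, 111) + 1] <- c(55, 80, 80, 55)
  counts[112:122 + 1] <- 60
  h3 <- hist_from_counts(counts)
  a3 <- apex_brightness(h3)
  expect_gt(abs(a3$I_Hbar - h3$I_H), 3)
  expect_equal(a3$I_h, a3$I_Hbar)
})

test_that("tailing factor is exactly 1 for symmetric histograms", {
  expect_equal(tailing_factor(hist_from_counts(triangle_counts(120)))$t_f, 1)
  # symmetric two-sided geometric decay
  counts <- numeric(256)
  counts[130 + 1] <- 4000
  for (d in 1:25) counts[c(130 - d, 130 + d) + 1] <- round(4000 * 0.7^d)
  expect_equal(tailing_factor(hist_from_counts(counts))$t_f, 1)
})

test_that("right-tail mass raises the tailing factor monotonically", {
  # tail mass must be contiguous with the peak (the crossing scan walks
  # outward from the apex and stops at the first bin below f*H) and stay
  # below half height, or it would widen the FWHM window and legitimately
  # move the redefined apex instead
  base <- triangle_counts(120, half_width = 30)
  tf <- sapply(c(0, 30, 60, 120), function(extra) {
    counts <- base
    counts[130:200 + 1] <- counts[130:200 + 1] + extra
    tailing_factor(hist_from_counts(counts))$t_f
  })
  expect_gt(tf[2], tf[1])
  expect_true(all(diff(tf) >= -1e-12))
})

test_that("tailing factor agrees with the brute-force oracle", {
  set.seed(12)
  n_checked <- 0
  while (n_checked < 300) {
    counts <- rand_unimodal_counts()
    t1 <- tryCatch(suppressWarnings(tailing_factor(hist_from_counts(counts))$t_f),
                   error = function(e) NULL)
    if (is.null(t1)) next
    expect_equal(t1, suppressWarnings(tailing_oracle(counts)), tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("degenerate peaks raise an explicit error", {
  counts <- numeric(256)
  counts[1] <- 100   # apex at brightness 0: no leading side
  expect_error(suppressWarnings(tailing_factor(hist_from_counts(counts))),
               "degenerate peak")
  # profile never falling below the level clamps the crossing with a warning
  # (once for the half-height scan, once for the f-level scan)
  edge <- triangle_counts(250, half_width = 30)
  expect_warning(
    expect_warning(tf <- tailing_factor(hist_from_counts(edge)), "clamped"),
    "clamped"
  )
  expect_true(is.finite(tf$t_f))
  expect_error(tailing_factor(hist_from_counts(triangle_counts()), f = 0.7), "f")
})

test_that("end-to-end scoring is deterministic and ranks damage correctly", {
  clean <- generate_fixture(fixture_spec(seed = 21, angle = 12))
  dmg <- generate_fixture(fixture_spec(seed = 21, angle = 12,
                                       n_clusters = 20, n_rings = 6, n_specks = 30))
  s_clean <- score_image(clean$image, clean$axis, clean$diagonal)
  s_dmg <- score_image(dmg$image, dmg$axis, dmg$diagonal)
  expect_gt(s_dmg$tailing_factor, s_clean$tailing_factor)
  # clean control band: near-symmetric histogram
  expect_lt(s_clean$tailing_factor, 1.6)
  expect_gt(s_clean$tailing_factor, 0.8)
  # determinism
  again <- score_image(clean$image, clean$axis, clean$diagonal)
  expect_identical(s_clean, again)
})
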