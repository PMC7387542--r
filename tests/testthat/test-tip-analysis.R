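quarter_circle <- function(r = 20, n = 40) {
  th <- seq(0, pi / 2, length.out = n)
  pf_trace(z = r * sin(th), x = r * (1 - cos(th)))
}

test_that("smoothing leaves straight lines unchanged and recovers arc curvature", {
  tr <- pf_trace(z = seq(0, 40, by = 2), x = rep(0, 21))
  expect_lt(max(abs(smooth_trace(tr)$x - tr$x)), 1e-6)

  arc <- quarter_circle()
  sm <- smooth_trace(arc)
  m <- curl_metrics(sm, origin = list(origin_index = 1, blunt = FALSE))
  expect_equal(m$curvature, 0.05, tolerance = 0.02)
  expect_error(smooth_trace(pf_trace(z = c(0, 1, 2), x = c(0, 0, 0))),
               ">= 4 points")
})

test_that("curl origin finds the departure point and flags blunt traces", {
  # straight wall to z = 50, then an arc outward (curvature 0.05)
  th <- seq(0.05, 1.2, by = 0.05)
  tr <- pf_trace(z = c(seq(0, 50, by = 2), 50 + 20 * sin(th)),
                 x = c(rep(0, 26), 20 * (1 - cos(th))))
  o <- curl_origin(tr)
  expect_false(o$blunt)
  expect_equal(o$origin_z, 50)
  # axial translation equivariance
  tr2 <- tr; tr2$z <- tr2$z + 123
  expect_equal(curl_origin(tr2)$origin_z, 173)
  # fully in-wall trace is blunt with curl length 0
  w <- pf_trace(z = seq(0, 60, by = 4), x = rep(0, 16))
  ow <- curl_origin(w)
  expect_true(ow$blunt)
  expect_equal(curl_metrics(w, ow)$length, 0)
})

test_that("curl metrics: quarter circle geometry and scaling law", {
  arc <- quarter_circle()
  m <- curl_metrics(arc, origin = list(origin_index = 1, blunt = FALSE))
  expect_equal(m$length, 10 * pi, tolerance = 0.01)
  expect_equal(m$curvature, 0.05, tolerance = 0.001)
  # straight "curl" has zero curvature
  s <- pf_trace(z = seq(0, 20, by = 2), x = seq(0, 10, by = 1))
  ms <- curl_metrics(s, origin = list(origin_index = 1, blunt = FALSE))
  expect_equal(ms$curvature, 0, tolerance = 1e-12)
  # doubling all coordinates doubles length, halves curvature
  arc2 <- arc; arc2$z <- 2 * arc2$z; arc2$x <- 2 * arc2$x
  m2 <- curl_metrics(arc2, origin = list(origin_index = 1, blunt = FALSE))
  expect_equal(m2$length, 2 * m$length, tolerance = 1e-9)
  expect_equal(m2$curvature, m$curvature / 2, tolerance = 1e-9)
})

test_that("raggedness is the sample sd of curl origins", {
  expect_equal(raggedness(c(0, 6, 12)), 6.0)
  expect_identical(raggedness(c(4, 4, 4, 4)), 0)
  expect_equal(raggedness(c(0, 6, 12) + 100), 6.0)  # shift invariance
  expect_error(raggedness(5), ">= 2")
})

test_that("fixture traces round-trip and metrics recover ground truth", {
  fx <- make_fixture_traces(n_mt = 4, curvature = 0.05, curl_length = 30,
                            origin_spread = 6, noise_sd = 0, seed = 3)
  tm <- tip_metrics(fx$traces, smooth = FALSE)
  expect_equal(nrow(tm), nrow(fx$truth))
  expect_lt(mean(abs(tm$curl_length - fx$truth$curl_length) /
                   fx$truth$curl_length), 0.1)
  expect_lt(mean(abs(tm$curvature - fx$truth$curvature) /
                   fx$truth$curvature), 0.1)
  expect_lt(mean(abs(tm$origin_z - fx$truth$origin_z)), 3)

  # file round trip preserves everything
  f <- tempfile(fileext = ".tsv")
  write_traces(fx$traces, f)
  back <- read_traces(f)
  expect_equal(length(back), length(fx$traces))
  expect_equal(back[[7]]$z, fx$traces[[7]]$z)
  expect_equal(back[[7]]$x, fx$traces[[7]]$x)

  # seeded determinism: identical file hash
  f2 <- tempfile(fileext = ".tsv")
  make_fixture_traces(n_mt = 2, seed = 9, file = f2)
  h1 <- unname(tools::md5sum(f2))
  make_fixture_traces(n_mt = 2, seed = 9, file = f2)
  expect_identical(unname(tools::md5sum(f2)), h1)
})

test_that("parameter recovery stays under 10% across the fixture grid", {
  errs_len <- c(); errs_cur <- c()
  for (cv in c(0.02, 0.04, 0.06)) for (cl in c(20, 50, 80)) {
    fx <- make_fixture_traces(n_mt = 2, n_pf = 6, curvature = cv,
                              curl_length = cl, origin_spread = 4,
                              noise_sd = 0.8, seed = round(1000 * cv + cl))
    tm <- tip_metrics(fx$traces, span = 0.5)
    errs_len <- c(errs_len, abs(mean(tm$curl_length) - cl) / cl)
    errs_cur <- c(errs_cur, abs(mean(tm$curvature, na.rm = TRUE) - cv) / cv)
  }
  expect_lt(mean(errs_len), 0.1)
  expect_lt(mean(errs_cur), 0.1)
})

test_that("neighbor correlation pools adjacent pairs and handles ties", {
  # smoothly varying metric around the ring -> strong positive rank
  # correlation between neighbours
  tm <- data.frame(mt_id = 1, pf_index = 0:12,
                   curl_length = 40 + 30 * sin(2 * pi * (0:12) / 13),
                   curvature = 0.05, origin_z = 0, blunt = FALSE)
  nc <- neighbor_correlation(tm, "length")
  expect_gt(nc$r_s, 0.5)
  expect_lt(nc$p, 0.01)
  expect_equal(nc$n_pairs, 13)
  # identical values -> flagged, not an error
  tm$curl_length <- 5
  expect_true(neighbor_correlation(tm, "length")$all_ties)
  # too few pairs -> error
  expect_error(neighbor_correlation(tm[1:3, ], "length"), "adjacent pairs")
})

test_that("raggedness per MT handles partial rings", {
  fx <- make_fixture_traces(n_mt = 3, n_pf = 5, origin_spread = 6,
                            seed = 4)
  tm <- tip_metrics(fx$traces, smooth = FALSE)
  rg <- mt_raggedness(tm)
  expect_equal(nrow(rg), 3)
  expect_true(all(rg$n_pf == 5))
  expect_true(all(rg$raggedness > 0))
})
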