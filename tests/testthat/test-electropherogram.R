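test_that("ladder calibration is log-linear, exact at knots, monotone between", {
  cal <- calibrate_ladder(data.frame(time = c(10, 20), size_bp = c(100, 1000)))
  expect_equal(cal$size_of(15), 10^2.5, tolerance = 1e-9)   # 316.23 bp
  expect_equal(cal$size_of(10), 100, tolerance = 1e-9)
  expect_equal(cal$size_of(20), 1000, tolerance = 1e-9)
  # property: random strictly monotone ladders, exact at every knot and
  # monotone on a fine grid spanning the ladder
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    tt <- sort(runif(k, 0, 100))
    ss <- sort(runif(k, 50, 1500))
    if (any(diff(tt) < 1e-3) || any(diff(ss) < 1e-3)) next
    cal <- calibrate_ladder(data.frame(time = tt, size_bp = ss))
    expect_equal(cal$size_of(tt), ss, tolerance = 1e-8)
    grid <- seq(tt[1], tt[k], length.out = 200)
    expect_true(all(diff(cal$size_of(grid)) > 0))
  }
})

test_that("calibration rejects degenerate ladders and warns on extrapolation", {
  expect_error(calibrate_ladder(data.frame(time = 10, size_bp = 100)), "two")
  expect_error(calibrate_ladder(data.frame(time = c(10, 10), size_bp = c(100, 200))),
               "increasing")
  expect_error(calibrate_ladder(data.frame(time = c(10, 20), size_bp = c(200, 100))),
               "increasing")
  cal <- calibrate_ladder(data.frame(time = c(10, 20), size_bp = c(100, 1000)))
  expect_warning(v <- cal$size_of(25), "extrapolat")
  expect_equal(v, 10^3.5, tolerance = 1e-9)  # terminal slope continued
})

test_that("peak detection integrates an isolated Gaussian to its analytic area", {
  tr <- make_gaussian_trace(centers = 25, amps = 100, sds = 1.0)
  pk <- detect_peaks(tr, min_height = 10, min_separation = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex_time, 25, tolerance = 0.02)
  analytic <- 100 * 1.0 * sqrt(2 * pi)   # A * sigma * sqrt(2*pi) = 250.66
  expect_lt(abs(pk$area - analytic) / analytic, 0.01)
})

test_that("a flat trace yields no peaks and an empty trace errors", {
  flat <- list(time = seq(0, 10, 0.1), signal = rep(0, 101))
  expect_equal(nrow(detect_peaks(flat, min_height = 1)), 0)
  expect_error(detect_peaks(list(time = numeric(0), signal = numeric(0))), "empty")
  expect_error(detect_peaks(list(time = 1:3, signal = 1:2)), "length")
})

test_that("peaks closer than min_separation merge at the taller apex", {
  tr <- make_gaussian_trace(centers = c(20, 30), amps = c(80, 100), sds = 1.5)
  merged <- detect_peaks(tr, min_height = 10, min_separation = 20)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$apex_time, 30, tolerance = 0.05)
  # the merged valley-to-valley area covers both components
  both <- (80 + 100) * 1.5 * sqrt(2 * pi)
  expect_lt(abs(merged$area - both) / both, 0.02)
  split <- detect_peaks(tr, min_height = 10, min_separation = 5)
  expect_equal(nrow(split), 2)
})

test_that("peak areas are stable under uniform grid refinement", {
  coarse <- make_gaussian_trace(c(15, 35), c(60, 90), 1.2,
                                grid = seq(0, 50, by = 0.05))
  fine <- make_gaussian_trace(c(15, 35), c(60, 90), 1.2,
                              grid = seq(0, 50, by = 0.01))
  a1 <- detect_peaks(coarse, min_height = 10)$area
  a2 <- detect_peaks(fine, min_height = 10)$area
  expect_equal(length(a1), 2)
  expect_true(all(abs(a1 - a2) / a2 < 0.005))
})

test_that("amplicon assignment matches nearest in-window peaks", {
  ase <- smn_ase()  # expected exclusion 276 / inclusion 330
  # both peaks close to their expected sizes: both slots filled
  pk <- data.frame(called_size_bp = c(270, 331), area = c(5, 6))
  got <- assign_amplicons(pk, ase, rel_tol = 0.10)
  expect_equal(got$exclusion$called_size_bp, 270)
  expect_equal(got$inclusion$called_size_bp, 331)
  # one far-off peak: both slots missing
  none <- assign_amplicons(data.frame(called_size_bp = 500, area = 1), ase, 0.10)
  expect_null(none$inclusion)
  expect_null(none$exclusion)
  # two candidates for the exclusion slot: nearest wins
  pk2 <- data.frame(called_size_bp = c(300, 302), area = c(10, 5))
  got2 <- assign_amplicons(pk2, ase, rel_tol = 0.10)
  expect_equal(got2$exclusion$called_size_bp, 300)
  # equal distance: the larger area wins
  pk3 <- data.frame(called_size_bp = c(272, 280), area = c(2, 9))
  got3 <- assign_amplicons(pk3, ase, rel_tol = 0.10)
  expect_equal(got3$exclusion$called_size_bp, 280)
})

test_that("ambiguously close expected sizes are a configuration error", {
  close_ase <- data.frame(ase_id = "x", gene = "X", size_inclusion_bp = 310L,
                          size_exclusion_bp = 300L, inclusion_is_long = TRUE)
  expect_error(assign_amplicons(data.frame(called_size_bp = 305, area = 1),
                                close_ase, rel_tol = 0.10), "ambiguous")
})

test_that("molar correction divides area by called size", {
  expect_equal(quantify_molar(data.frame(called_size_bp = 330, area = 330)), 1.0)
  expect_equal(quantify_molar(data.frame(called_size_bp = 330, area = 300)),
               0.9091, tolerance = 1e-4)
  expect_error(quantify_molar(data.frame(called_size_bp = 0, area = 1)), "positive")
  expect_true(is.na(quantify_molar(NULL)))
})
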