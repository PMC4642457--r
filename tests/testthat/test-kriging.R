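vg <- list(model = "exponential", range = 800, sill = 0.04, nugget = 0)

andes_points <- tibble::tibble(
  lat = c(-12.0, -16.5, -17.4, -33.4, -0.2, 4.7),
  lon = c(-77.0, -68.1, -66.2, -70.6, -78.5, -74.1),
  freq = c(0.45, 0.30, 0.25, 0.10, 0.20, 0.05),
  n = c(120, 80, 60, 90, 70, 100)
)

test_that("with zero nugget the surface interpolates the data exactly", {
  surf <- krige_frequencies(andes_points,
                            grid = andes_points[, c("lat", "lon")],
                            variogram = vg)
  expect_equal(surf$freq, andes_points$freq, tolerance = 1e-8)
  expect_lt(max(abs(surf$kriging_variance)), 1e-6)
})

test_that("kriging weights sum to one at every grid node", {
  surf <- krige_frequencies(andes_points, n_grid = 12, variogram = vg)
  expect_equal(nrow(surf), 144)
  expect_equal(max(abs(attr(surf, "weight_sums") - 1)), 0, tolerance = 1e-9)
})

test_that("a constant field predicts the constant everywhere", {
  pts <- andes_points
  pts$freq <- 0.37
  surf <- krige_frequencies(pts, n_grid = 6, variogram = vg)
  expect_equal(surf$freq, rep(0.37, nrow(surf)), tolerance = 1e-8)
})

test_that("two-point prediction matches the hand-solved kriging system", {
  pts <- tibble::tibble(lat = c(0, 0), lon = c(0, 10), freq = c(0.2, 0.6))
  target <- tibble::tibble(lat = 0, lon = 5)
  d12 <- geosphere::distHaversine(c(0, 0), c(10, 0)) / 1000
  d0 <- geosphere::distHaversine(c(0, 0), c(5, 0)) / 1000
  g <- function(h) vg$sill * (1 - exp(-h / vg$range))
  # symmetric 2x2 ordinary-kriging system: equal distances -> w = (1/2, 1/2)
  # closed form: w1 = 1/2 + (g(d02) - g(d01)) / (2 g(d12)); here d01 = d02
  expect_equal(g(d0), g(d0))
  surf <- krige_frequencies(pts, grid = target, variogram = vg)
  expect_equal(surf$freq, 0.4, tolerance = 1e-10)
  # asymmetric target: solve the bordered system by hand and compare
  target2 <- tibble::tibble(lat = 0, lon = 3)
  d01 <- geosphere::distHaversine(c(0, 0), c(3, 0)) / 1000
  d02 <- geosphere::distHaversine(c(10, 0), c(3, 0)) / 1000
  A <- rbind(c(0, g(d12), 1), c(g(d12), 0, 1), c(1, 1, 0))
  sol <- solve(A, c(g(d01), g(d02), 1))
  hand <- sum(sol[1:2] * pts$freq)
  surf2 <- krige_frequencies(pts, grid = target2, variogram = vg)
  expect_equal(surf2$freq, hand, tolerance = 1e-10)
})

test_that("predictions are clipped to [0, 1] and singular inputs are reported", {
  pts <- tibble::tibble(lat = c(0, 1, 2), lon = c(0, 1, 2),
                        freq = c(0, 1, 1))
  surf <- krige_frequencies(pts, n_grid = 8, variogram = vg)
  expect_true(all(surf$freq >= 0 & surf$freq <= 1))
  dup <- tibble::tibble(lat = c(0, 0), lon = c(0, 0), freq = c(0.1, 0.9))
  expect_error(krige_frequencies(dup, variogram = vg), "coincident")
})

test_that("the fitted variogram is exponential with positive parameters", {
  fit <- fit_variogram(andes_points)
  expect_equal(fit$model, "exponential")
  expect_gt(fit$range, 0)
  expect_gt(fit$sill, 0)
  expect_equal(fit$nugget, 0)
  surf <- krige_frequencies(andes_points, n_grid = 5)
  expect_true(all(is.finite(surf$freq)))
})
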