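#' Ordinary kriging of haplogroup frequencies
#'
#' Interpolates point frequencies onto a regular latitude/longitude grid by
#' ordinary kriging: at each grid node the weights solve the standard
#' constrained system (semivariogram matrix bordered with the unbiasedness
#' constraint, so weights sum to 1). Distances are great-circle kilometres.
#' With a zero nugget the surface interpolates the data exactly; predictions
#' are clipped to `[0, 1]`.
#'
#' @param points Tibble with columns `lat`, `lon`, `freq` (and optionally
#'   `n`, the sample size behind each frequency).
#' @param grid Either a tibble of `lat`, `lon` prediction nodes or `NULL`
#'   to build a regular grid covering the points.
#' @param variogram A list `(model, range, sill, nugget)`; only the
#'   exponential model is currently implemented. `NULL` fits one with
#'   [fit_variogram()].
#' @param n_grid Nodes per axis when `grid` is `NULL`.
#' @return A tibble of class `freq_surface` with columns `lat`, `lon`,
#'   `freq`, `kriging_variance`; the variogram used and the per-node weight
#'   sums are attached as attributes (`variogram`, `weight_sums`).
#' @export
krige_frequencies <- function(points, grid = NULL, variogram = NULL,
                              n_grid = 25L) {
  stopifnot(all(c("lat", "lon", "freq") %in% names(points)))
  if (nrow(points) < 2) abort("kriging needs at least 2 points")
  dup <- duplicated(points[, c("lat", "lon")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("coincident points at (%.4f, %.4f) make the system singular",
                  points$lat[i], points$lon[i]))
  }
  if (is.null(variogram)) variogram <- fit_variogram(points)
  if (!identical(variogram$model, "exponential"))
    abort("only the exponential variogram model is implemented")
  if (is.null(grid)) {
    grid <- tidyr::expand_grid(
      lat = seq(min(points$lat), max(points$lat), length.out = n_grid),
      lon = seq(min(points$lon), max(points$lon), length.out = n_grid)
    )
  }

  gamma <- function(h) {
    (variogram$nugget + variogram$sill * (1 - exp(-h / variogram$range))) *
      (h > 0)  # gamma(0) = 0 by definition; the nugget is the h -> 0+ limit
  }
  n <- nrow(points)
  D <- haversine_matrix(points$lat, points$lon, points$lat, points$lon)
  A <- rbind(cbind(gamma(D), 1), c(rep(1, n), 0))
  Ai <- tryCatch(solve(A), error = function(e)
    abort("singular kriging system; check for (near-)coincident points"))

  D0 <- haversine_matrix(points$lat, points$lon, grid$lat, grid$lon)
  B <- rbind(gamma(D0), 1)            # (n+1) x n_nodes
  sol <- Ai %*% B
  W <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- as.numeric(crossprod(W, points$freq))
  kvar <- pmax(0, colSums(B[seq_len(n), , drop = FALSE] * W) + mu)

  out <- tibble(lat = grid$lat, lon = grid$lon,
                freq = pmin(1, pmax(0, pred)),
                kriging_variance = kvar)
  attr(out, "variogram") <- variogram
  attr(out, "weight_sums") <- colSums(W)
  class(out) <- c("freq_surface", class(out))
  out
}

haversine_matrix <- function(lat1, lon1, lat2, lon2) {
  m <- matrix(0, length(lat1), length(lat2))
  for (j in seq_along(lat2)) {
    m[, j] <- geosphere::distHaversine(cbind(lon1, lat1),
                                       c(lon2[j], lat2[j])) / 1000
  }
  m
}

#' Fit an exponential variogram by the method of moments
#'
#' Computes the classical (Matheron) empirical semivariogram on distance
#' bins, then least-squares fits the exponential model with zero nugget.
#'
#' @param points Tibble with `lat`, `lon`, `freq`.
#' @param n_bins Number of distance bins.
#' @return A variogram list `(model, range, sill, nugget)`.
#' @export
fit_variogram <- function(points, n_bins = 8L) {
  D <- haversine_matrix(points$lat, points$lon, points$lat, points$lon)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[iu]
  g <- (points$freq[iu[, 1]] - points$freq[iu[, 2]])^2 / 2
  bins <- cut(h, breaks = n_bins)
  emp <- tibble(h = tapply(h, bins, mean), gamma = tapply(g, bins, mean))
  emp <- emp[stats::complete.cases(emp), , drop = FALSE]
  sill0 <- max(stats::var(points$freq), 1e-6)
  range0 <- max(stats::median(h), 1)
  obj <- function(p) {
    fit <- p[2] * (1 - exp(-emp$h / p[1]))
    sum((fit - emp$gamma)^2)
  }
  opt <- stats::optim(c(range0, sill0), obj, method = "L-BFGS-B",
                      lower = c(1e-3, 1e-8))
  list(model = "exponential", range = opt$par[1], sill = opt$par[2], nugget = 0)
}

#' @export
autoplot.freq_surface <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$freq)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = "frequency") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points,
                                 ggplot2::aes(size = .data$n),
                                 colour = "white", shape = 21)
  }
  p
}

#' Read / write geographic frequency points and surfaces
#'
#' @param path CSV with columns `lat`, `lon`, `freq`, optionally `n`.
#' @return `read_geo_points()`: a tibble.
#' @export
read_geo_points <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                  comment = "#")
}

#' @rdname read_geo_points
#' @param surface A `freq_surface`.
#' @export
write_surface <- function(surface, path) {
  readr::write_csv(as_tibble(surface), path)
  invisible(path)
}
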