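#' Visual-field pixel grid
#'
#' A square pixel grid in degrees of visual angle, symmetric about fixation
#' (the origin). The default covers the circular display aperture
#' (9.15 degree radius) at roughly 0.1 degree per pixel. Coordinates follow
#' the package-wide convention: x rightward, y upward, polar angle
#' counterclockwise from the positive x axis.
#'
#' @param half_extent Half-width of the grid in degrees (default 9.15, the
#'   aperture radius).
#' @param n_pixels Number of pixels per side (>= 32; default 183, i.e. 0.1
#'   degree pixels).
#' @return An object of class `vf_grid` with fields `half_extent`,
#'   `n_pixels`, `pixel_size`, `px` (the per-axis pixel-center coordinates)
#'   and `coords` (an `n_pixels^2` x 2 matrix of pixel centers, row-major in
#'   y-then-x order).
#' @export
visual_field_grid <- function(half_extent = 9.15, n_pixels = 183L) {
  stopifnot(is.numeric(half_extent), length(half_extent) == 1L, half_extent > 0)
  n_pixels <- as.integer(n_pixels)
  if (is.na(n_pixels) || n_pixels < 32L)
    stop("n_pixels must be an integer >= 32")
  pixel_size <- 2 * half_extent / n_pixels
  px <- seq(-half_extent + pixel_size / 2, half_extent - pixel_size / 2,
            length.out = n_pixels)
  coords <- cbind(x = rep(px, times = n_pixels),
                  y = rep(px, each = n_pixels))
  structure(list(half_extent = half_extent, n_pixels = n_pixels,
                 pixel_size = pixel_size, px = px, coords = coords),
            class = "vf_grid")
}

#' Spatial filter profile
#'
#' Radial sensitivity profile of one information channel: a raised cosine
#' taken to the 7th power, `(0.5 + 0.5*cos(pi*r/s))^7` for `r < s` and 0
#' beyond. `s` is the size constant: the distance from the filter center at
#' which sensitivity falls to zero.
#'
#' @param r Distance(s) from the filter center, degrees (>= 0).
#' @param s Size constant, degrees (> 0).
#' @param exponent Power applied to the raised cosine (default 7).
#' @return Activation value(s) in `[0, 1]`.
#' @export
filter_profile <- function(r, s, exponent = 7) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0)
    stop("size constant s must be a single positive number")
  if (any(r < 0, na.rm = TRUE)) stop("r must be nonnegative")
  out <- numeric(length(r))
  inside <- r < s
  out[inside] <- (0.5 + 0.5 * cos(pi * r[inside] / s))^exponent
  out
}

#' Centered hexagonal (triangular) grid of points
#'
#' Builds the origin plus `n_rings` concentric hexagonal rings of a
#' triangular lattice with nearest-neighbor distance `spacing`. The point
#' count is the centered-hexagonal number `3*n(n+1) + 1` (37 for
#' `n_rings = 3`).
#'
#' @param spacing Lattice constant (nearest-neighbor distance), degrees.
#' @param n_rings Number of rings around the center (>= 0).
#' @param center Length-2 numeric, grid center (default fixation).
#' @return A k x 2 matrix of point coordinates.
#' @export
build_triangular_grid <- function(spacing, n_rings, center = c(0, 0)) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  n_rings <- as.integer(n_rings)
  if (is.na(n_rings) || n_rings < 0L) stop("n_rings must be >= 0")
  # axial hex coordinates (q, r) with max(|q|, |r|, |q + r|) <= n_rings
  qr <- expand.grid(q = -n_rings:n_rings, r = -n_rings:n_rings)
  keep <- pmax(abs(qr$q), abs(qr$r), abs(qr$q + qr$r)) <= n_rings
  qr <- qr[keep, , drop = FALSE]
  x <- spacing * (qr$q + qr$r / 2)
  y <- spacing * (sqrt(3) / 2) * qr$r
  # order by ring then angle for reproducible channel indexing
  ring <- pmax(abs(qr$q), abs(qr$r), abs(qr$q + qr$r))
  ord <- order(ring, atan2(y, x))
  pts <- cbind(x = x[ord] + center[1], y = y[ord] + center[2])
  rownames(pts) <- NULL
  pts
}

#' Rotate points in the visual field
#'
#' Planar rotation about a pivot; positive angles rotate counterclockwise,
#' angles in degrees.
#'
#' @param points An n x 2 matrix (or length-2 vector) of coordinates.
#' @param angle Rotation angle in degrees.
#' @param pivot Length-2 pivot point (default fixation).
#' @return Rotated coordinates, same shape as `points`.
#' @export
rotate_points <- function(points, angle, pivot = c(0, 0)) {
  was_vec <- is.null(dim(points))
  if (was_vec) points <- matrix(points, ncol = 2)
  stopifnot(ncol(points) == 2, all(is.finite(points)), is.finite(angle))
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- sweep(sweep(points, 2, pivot) %*% t(R), 2, pivot, `+`)
  colnames(out) <- c("x", "y")
  if (was_vec) out <- drop(out)
  out
}

#' Spatial channel basis
#'
#' The basis set of k identically shaped spatial filters arrayed on a
#' triangular grid. Defaults give the 37-channel layout: 3 rings at 2.83
#' degree spacing centered at fixation. The size constant defaults to
#' 1.25 x spacing so that neighboring filters overlap substantially.
#'
#' @param spacing Center-to-center filter spacing, degrees (default 2.83).
#' @param n_rings Number of hexagonal rings (default 3, giving 37 filters).
#' @param size_constant Filter size constant s, degrees (default
#'   `1.25 * spacing`).
#' @param exponent Raised-cosine power (default 7).
#' @param center Grid center (default fixation).
#' @return Object of class `channel_basis` with fields `centers` (k x 2),
#'   `spacing`, `size_constant`, `exponent`, `n_rings`.
#' @export
channel_basis <- function(spacing = 2.83, n_rings = 3L,
                          size_constant = 1.25 * spacing, exponent = 7,
                          center = c(0, 0)) {
  if (size_constant <= 0) stop("size_constant must be > 0")
  centers <- build_triangular_grid(spacing, n_rings, center)
  structure(list(centers = centers, spacing = spacing,
                 size_constant = size_constant, exponent = exponent,
                 n_rings = as.integer(n_rings)),
            class = "channel_basis")
}

#' @export
print.channel_basis <- function(x, ...) {
  cat(sprintf("channel basis: %d filters, spacing %.3g deg, size constant %.3g deg, cos^%g profile\n",
              nrow(x$centers), x$spacing, x$size_constant, x$exponent))
  invisible(x)
}

#' Render the channel basis on a pixel grid
#'
#' Evaluates each filter's sensitivity profile at every pixel center,
#' producing the p pixels x k channels matrix used both to convert stimulus
#' masks into channel activations and to render reconstructed maps.
#'
#' @param basis A [channel_basis()].
#' @param grid A [visual_field_grid()].
#' @return A p x k numeric matrix.
#' @export
render_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "channel_basis"), inherits(grid, "vf_grid"))
  dx <- outer(grid$coords[, 1], basis$centers[, 1], `-`)
  dy <- outer(grid$coords[, 2], basis$centers[, 2], `-`)
  filter_profile(c(sqrt(dx^2 + dy^2)), basis$size_constant, basis$exponent) |>
    matrix(nrow = nrow(grid$coords), ncol = nrow(basis$centers))
}

#' Binary stimulus mask
#'
#' Contrast mask of a circular disc stimulus on the pixel grid: 1 for pixels
#' whose centers fall within `radius` of the stimulus center and inside the
#' display aperture, 0 elsewhere.
#'
#' @param grid A [visual_field_grid()].
#' @param center Length-2 stimulus center, degrees.
#' @param radius Stimulus radius, degrees (default 1.5).
#' @return Object of class `stim_mask` with fields `grid`, `values`
#'   (length-p 0/1 vector), `center`, `radius`.
#' @export
stimulus_mask <- function(grid, center, radius = 1.5) {
  stopifnot(inherits(grid, "vf_grid"), length(center) == 2, radius > 0)
  d2 <- (grid$coords[, 1] - center[1])^2 + (grid$coords[, 2] - center[2])^2
  ecc2 <- grid$coords[, 1]^2 + grid$coords[, 2]^2
  values <- as.numeric(d2 <= radius^2 & ecc2 <= grid$half_extent^2)
  structure(list(grid = grid, values = values, center = as.numeric(center),
                 radius = radius),
            class = "stim_mask")
}

#' Convert stimulus masks to a channel design matrix
#'
#' Takes the dot product of each vectorized stimulus mask (n trials x p
#' pixels) with the filter sensitivity profiles (p pixels x k channels),
#' then rescales so the maximum activation over the whole design matrix is
#' 1 (one global scale, preserving relative trial amplitudes;
#' `per_trial = TRUE` instead normalizes each trial row to max 1).
#'
#' @param masks A list of [stimulus_mask()] objects sharing one grid, or an
#'   n x p 0/1 matrix.
#' @param filter_matrix The p x k matrix from [render_basis()].
#' @param per_trial Normalize each row separately instead of globally.
#' @return Object of class `design_matrix` with fields `values` (n x k) and
#'   `normalization_scale`.
#' @export
masks_to_channels <- function(masks, filter_matrix, per_trial = FALSE) {
  if (is.list(masks) && !is.matrix(masks)) {
    stopifnot(all(vapply(masks, inherits, logical(1), "stim_mask")))
    p <- vapply(masks, function(m) m$grid$n_pixels, integer(1))
    if (length(unique(p)) != 1L) stop("all masks must share one grid")
    M <- do.call(rbind, lapply(masks, `[[`, "values"))
  } else {
    M <- as.matrix(masks)
  }
  if (ncol(M) != nrow(filter_matrix))
    stop("mask length does not match the filter matrix pixel count")
  raw <- M %*% filter_matrix
  mx <- max(raw)
  if (mx <= 0)
    stop("all-zero design: no stimulus mask overlaps any filter's support")
  if (per_trial) {
    row_mx <- apply(raw, 1, max)
    if (any(row_mx <= 0))
      stop("per-trial normalization: some trial overlaps no filter")
    values <- raw / row_mx
    scale <- NA_real_
  } else {
    values <- raw / mx
    scale <- 1 / mx
  }
  structure(list(values = values, normalization_scale = scale),
            class = "design_matrix")
}
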