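#' Attach physical metadata to an intensity array
#'
#' Images throughout the package are plain numeric arrays (y, x) in 2D or
#' (y, x, z) in 3D, with physical metadata carried as attributes. Movies are
#' arrays with one extra trailing time dimension, flagged by `time_axis`.
#'
#' @param data numeric array.
#' @param pixel_size_um physical size of one pixel/voxel edge, in micrometres.
#'   A scalar (isotropic) or one value per spatial dimension.
#' @param frame_interval_s time between frames in seconds (movies only).
#' @param time_axis integer index of the time dimension, or `NA` for a single
#'   frame.
#' @return the array with `pixel_size_um`, `frame_interval_s` and `time_axis`
#'   attributes set.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_s = NA_real_,
                        time_axis = NA_integer_) {
  stopifnot(is.numeric(data), is.array(data) || is.matrix(data),
            all(pixel_size_um > 0))
  attr(data, "pixel_size_um") <- pixel_size_um
  attr(data, "frame_interval_s") <- frame_interval_s
  attr(data, "time_axis") <- time_axis
  data
}

#' @rdname image_stack
#' @param x an image created by [image_stack()] (a bare array is accepted and
#'   yields `default`).
#' @param default value returned when the attribute is missing.
#' @export
pixel_size <- function(x, default = 1) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) default else ps
}

## Spatial dimensions of a single frame (drops the time axis if present).
spatial_dim <- function(x) {
  d <- dim(x)
  ta <- attr(x, "time_axis")
  if (!is.null(ta) && !is.na(ta)) d <- d[-ta]
  d
}

## Extract frame i of a movie as a plain array with metadata preserved.
get_frame <- function(movie, i) {
  d <- dim(movie)
  ta <- attr(movie, "time_axis")
  if (is.null(ta) || is.na(ta)) stop("not a movie: no time axis")
  idx <- rep(list(quote(expr = )), length(d))
  idx[[ta]] <- i
  fr <- do.call(`[`, c(list(movie), idx, list(drop = FALSE)))
  dn <- dim(fr)[-ta]
  if (length(dn) == 1L) dn <- c(dn, 1L)
  fr <- array(as.numeric(fr), dn)
  image_stack(fr, pixel_size(movie))
}

n_frames <- function(movie) {
  ta <- attr(movie, "time_axis")
  if (is.null(ta) || is.na(ta)) 1L else dim(movie)[ta]
}

## Row-stochastic Gaussian smoothing matrix (renormalized at the borders so
## interior intensity is conserved).
blur_matrix <- function(n, sigma) {
  k <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = sigma)
  k / rowSums(k)
}

#' Gaussian blur of a 2D or 3D image
#'
#' Separable Gaussian convolution used as the point-spread-function model of
#' the synthetic generators. The smoothing kernel is renormalized at array
#' borders; away from the borders total intensity is conserved.
#'
#' @param x numeric matrix or 3D array.
#' @param sigma_px standard deviation of the Gaussian in pixels; `0` returns
#'   `x` unchanged.
#' @return blurred array of the same shape (attributes preserved).
#' @export
gaussian_blur <- function(x, sigma_px) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(x)
  a <- attributes(x)
  d <- dim(x)
  if (length(d) == 2L) {
    out <- blur_matrix(d[1], sigma_px) %*% x %*% t(blur_matrix(d[2], sigma_px))
  } else if (length(d) == 3L) {
    ky <- blur_matrix(d[1], sigma_px)
    kx <- blur_matrix(d[2], sigma_px)
    kz <- blur_matrix(d[3], sigma_px)
    out <- x
    for (k in seq_len(d[3])) out[, , k] <- ky %*% x[, , k] %*% t(kx)
    m <- matrix(out, d[1] * d[2], d[3])
    out <- array(m %*% t(kz), d)
  } else stop("only 2D or 3D images are supported")
  attributes(out) <- a
  out
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance; used for
#' foreground/background separation when no per-cell rule applies.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @return a scalar threshold; values strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - r[1]) / diff(r) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

## Shift an array along each dimension by `off` (integer vector), filling
## vacated entries with `fill`. Used by the label propagation below.
shift_array <- function(x, off, fill = 0) {
  d <- dim(x)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    if (off[k] >= 0) {
      src[[k]] <- seq_len(d[k] - off[k])
      dst[[k]] <- src[[k]] + off[k]
    } else {
      src[[k]] <- seq_len(d[k] + off[k]) - off[k]
      dst[[k]] <- seq_len(d[k] + off[k])
    }
    if (length(src[[k]]) == 0) return(array(fill, d))
  }
  out <- array(fill, d)
  if (length(d) == 2L) {
    out[dst[[1]], dst[[2]]] <- x[src[[1]], src[[2]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  }
  out
}

neighbor_offsets <- function(nd) {
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs[rowSums(abs(offs)) > 0, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' 8-connectivity in 2D and 26-connectivity in 3D, by iterative minimum-label
#' propagation (each foreground pixel starts with a unique label and adopts
#' the smallest label among its neighbours until convergence).
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape; `0` is background, objects are
#'   numbered `1..n` in order of their smallest linear index.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(!is.null(d), length(d) %in% c(2L, 3L))
  mask <- array(as.logical(mask), d)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  offs <- neighbor_offsets(length(d))
  repeat {
    cur <- lab
    acc <- lab
    for (k in seq_len(nrow(offs)))
      acc <- pmin(acc, shift_array(lab, offs[k, ], fill = Inf))
    acc[!mask] <- Inf
    lab <- acc
    if (identical(lab, cur)) break
  }
  u <- sort(unique(lab[is.finite(lab)]))
  out <- array(0L, d)
  out[is.finite(lab)] <- match(lab[is.finite(lab)], u)
  out
}

## Rasterize a filled disc (2D) or ball (3D) into logical array coordinates.
## center is in pixel units (1-based, can be fractional), r in pixels.
raster_ball <- function(d, center, r) {
  if (length(d) == 2L) {
    dy <- outer(seq_len(d[1]) - center[1], rep(1, d[2]))
    dx <- outer(rep(1, d[1]), seq_len(d[2]) - center[2])
    dy^2 + dx^2 <= r^2
  } else {
    ax <- lapply(seq_along(d), function(k) (seq_len(d[k]) - center[k])^2)
    arr <- array(0, d)
    arr <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    arr <- array(arr, d)
    arr <= r^2
  }
}

## Coverage-weighted (anti-aliased) disc: per-pixel coverage in [0, 1],
## approximated from the centre distance and rescaled so the summed
## coverage tracks pi r^2 down to sub-pixel radii, which binary
## rasterization cannot do.
raster_disc_cov <- function(d, center, r) {
  dy <- outer(seq_len(d[1]) - center[1], rep(1, d[2]))
  dx <- outer(rep(1, d[1]), seq_len(d[2]) - center[2])
  cov <- pmin(pmax(r - sqrt(dy^2 + dx^2) + 0.5, 0), 1)
  s <- sum(cov)
  if (s > 0) cov <- pmin(cov * pi * r^2 / s, 1)
  cov
}

## Rasterize a filled axis-aligned ellipse: semi-axes a (x) and b (y), px.
raster_ellipse <- function(d, center, a, b) {
  dy <- outer(seq_len(d[1]) - center[1], rep(1, d[2]))
  dx <- outer(rep(1, d[1]), seq_len(d[2]) - center[2])
  (dx / a)^2 + (dy / b)^2 <= 1
}

## Run a function with a temporarily fixed RNG seed (restoring the caller's
## RNG state). seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
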