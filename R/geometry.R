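#' Image geometry
#'
#' Declarative description of a reconstruction volume: the number of
#' channels (time frames, energy bins or colour planes), the spatial grid
#' and the physical voxel size.  The spatial shape is ordered
#' slowest-to-fastest, i.e. `(z,) y, x`; container arrays carry the channel
#' axis first, so an allocated image has dim `c(num_channels, shape)`.
#'
#' @param shape integer vector of 2 or 3 spatial extents, ordered
#'   `(z,) y, x`.
#' @param num_channels number of channels (>= 1).
#' @param voxel_size physical edge length per voxel axis; a scalar is
#'   recycled to all spatial axes.
#' @param channel_labels optional per-channel annotation: the frame index
#'   for dynamic data or the bin-centre energy in keV for spectral data.
#' @return an object of class `image_geometry`.
#' @export
image_geometry <- function(shape, num_channels = 1L, voxel_size = 1,
                           channel_labels = NULL) {
  shape <- as.integer(shape)
  num_channels <- as.integer(num_channels)
  if (length(shape) < 2L || length(shape) > 3L)
    stop("spatial shape must have 2 or 3 axes")
  if (any(shape < 1L) || num_channels < 1L)
    stop("all counts must be >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), length(shape))
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (!is.null(channel_labels) && length(channel_labels) != num_channels)
    stop("channel_labels length must equal num_channels")
  structure(list(shape = shape, num_channels = num_channels,
                 voxel_size = voxel_size, channel_labels = channel_labels),
            class = "image_geometry")
}

#' Acquisition geometry
#'
#' Describes the scanner: beam type, projection angles (degrees, as scanner
#' metadata typically is; converted to radians internally where needed),
#' the 1D detector panel and, for fan beam, the source distances.
#'
#' @param beam `"parallel2D"` or `"fan2D"`.
#' @param angles ordered projection angles in degrees.
#' @param num_bins number of detector bins.
#' @param pixel_size detector pixel pitch.
#' @param num_channels number of channels.
#' @param source_to_origin,source_to_detector fan-beam distances; must
#'   satisfy `0 < source_to_origin < source_to_detector`.
#' @return an object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(beam = c("parallel2D", "fan2D"), angles,
                                 num_bins, pixel_size = 1,
                                 num_channels = 1L,
                                 source_to_origin = NULL,
                                 source_to_detector = NULL) {
  beam <- match.arg(beam)
  angles <- as.numeric(angles)
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop("angles must be a non-empty finite vector")
  num_bins <- as.integer(num_bins)
  if (num_bins < 1L) stop("num_detector_bins must be >= 1")
  if (pixel_size <= 0) stop("detector pixel size must be > 0")
  num_channels <- as.integer(num_channels)
  if (num_channels < 1L) stop("num_channels must be >= 1")
  if (beam == "fan2D") {
    if (is.null(source_to_origin) || is.null(source_to_detector))
      stop("fan2D requires source_to_origin and source_to_detector")
    if (!(source_to_origin > 0 && source_to_origin < source_to_detector))
      stop("fan2D requires 0 < source_to_origin < source_to_detector")
  }
  structure(list(beam = beam, angles = angles, num_bins = num_bins,
                 pixel_size = as.numeric(pixel_size),
                 num_channels = num_channels,
                 source_to_origin = source_to_origin,
                 source_to_detector = source_to_detector),
            class = "acquisition_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("image_geometry:", x$num_channels, "channel(s),",
      paste(x$shape, collapse = " x "), "voxels, size",
      paste(signif(x$voxel_size, 4), collapse = " x "), "\n")
  invisible(x)
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("acquisition_geometry:", x$beam, "-", length(x$angles), "angles,",
      x$num_bins, "bins,", x$num_channels, "channel(s)\n")
  invisible(x)
}

geom_dim <- function(geom) {
  if (inherits(geom, "image_geometry")) c(geom$num_channels, geom$shape)
  else c(geom$num_channels, length(geom$angles), geom$num_bins)
}

#' Allocate a container for a geometry
#'
#' @param geometry an `image_geometry` or `acquisition_geometry`.
#' @param fill scalar fill value (finite).
#' @return a `mc_image` or `mc_sinogram` whose every entry equals `fill`.
#' @export
allocate <- function(geometry, fill = 0) {
  if (!is.finite(fill)) stop("fill value must be finite")
  vals <- array(as.numeric(fill), dim = geom_dim(geometry))
  if (inherits(geometry, "image_geometry")) mc_image(geometry, vals)
  else if (inherits(geometry, "acquisition_geometry")) mc_sinogram(geometry, vals)
  else stop("allocate: not a valid geometry")
}

#' Multichannel image container
#'
#' A scalar grid of shape `(num_channels, *spatial_shape)` tied to an
#' [image_geometry()].
#' @param geometry an `image_geometry`.
#' @param values array with dim `c(num_channels, shape)`.
#' @export
mc_image <- function(geometry, values) {
  stopifnot(inherits(geometry, "image_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geom_dim(geometry))))
    stop("values shape inconsistent with geometry")
  structure(list(geometry = geometry, values = values),
            class = c("mc_image", "mc_container"))
}

#' Multichannel sinogram container
#'
#' A scalar grid of shape `(num_channels, num_angles, num_bins)` tied to an
#' [acquisition_geometry()].
#' @param geometry an `acquisition_geometry`.
#' @param values array with dim `c(num_channels, num_angles, num_bins)`.
#' @export
mc_sinogram <- function(geometry, values) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geom_dim(geometry))))
    stop("values shape inconsistent with geometry")
  structure(list(geometry = geometry, values = values),
            class = c("mc_sinogram", "mc_container"))
}

#' @export
print.mc_container <- function(x, ...) {
  cat(class(x)[1], "dim", paste(dim(x$values), collapse = " x "),
      "range [", signif(min(x$values), 4), ",", signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' Default image geometry for an acquisition
#'
#' The default reconstruction grid is square with side equal to the number
#' of detector bins, channels copied from the acquisition; an override
#' replaces the spatial shape.
#'
#' @param acq an `acquisition_geometry`.
#' @param override_shape optional spatial shape replacing the default.
#' @param voxel_size voxel edge length (defaults to the detector pitch).
#' @export
default_image_geometry <- function(acq, override_shape = NULL,
                                   voxel_size = NULL) {
  stopifnot(inherits(acq, "acquisition_geometry"))
  shape <- if (is.null(override_shape)) rep(acq$num_bins, 2L)
           else as.integer(override_shape)
  if (any(shape < 1L)) stop("override shape must have positive counts")
  if (is.null(voxel_size)) voxel_size <- acq$pixel_size
  image_geometry(shape, num_channels = acq$num_channels,
                 voxel_size = voxel_size)
}

#' Equi-angular undersampling of a sinogram
#'
#' Retains projection angles at indices `offset, offset+step, ...`
#' (`offset` counted 0-based), updating the geometry's angle list; channel
#' and detector axes are untouched.  `step = 1, offset = 0` is the
#' identity.
#'
#' @param sino a `mc_sinogram`.
#' @param step undersampling step (positive integer, at most the number of
#'   angles).
#' @param offset 0-based starting index, `0 <= offset < step`.
#' @export
slice_angles <- function(sino, step, offset = 0L) {
  stopifnot(inherits(sino, "mc_sinogram"))
  step <- as.integer(step); offset <- as.integer(offset)
  n <- length(sino$geometry$angles)
  if (step <= 0L) stop("step must be a positive integer")
  if (step > n) stop("step exceeds the number of angles")
  if (offset < 0L || offset >= step) stop("offset must satisfy 0 <= offset < step")
  keep <- seq.int(1L + offset, n, by = step)
  g <- sino$geometry
  g$angles <- g$angles[keep]
  mc_sinogram(g, sino$values[, keep, , drop = FALSE])
}

#' Lambert-Beer negative-logarithm conversion
#'
#' Converts transmission measurements into attenuation line integrals:
#' `-log(transmission / flat)`.  `flat` is an optional per-bin flat-field
#' reference (defaults to 1).
#'
#' @param transmission a `mc_sinogram` of strictly positive transmission
#'   values (after flat-field division).
#' @param flat scalar or per-bin vector of reference intensities.
#' @export
negative_log <- function(transmission, flat = 1) {
  stopifnot(inherits(transmission, "mc_sinogram"))
  v <- transmission$values
  nb <- dim(v)[3]
  if (length(flat) == 1L) {
    v <- v / flat
  } else {
    if (length(flat) != nb) stop("flat reference must be scalar or per-bin")
    v <- sweep(v, 3L, flat, "/")
  }
  bad <- which(!(v > 0))
  if (length(bad))
    stop(sprintf("non-positive transmission at linear index %d", bad[1]))
  mc_sinogram(transmission$geometry, -log(v))
}

#' Extract one channel of a multichannel container
#'
#' @param x a `mc_image` or `mc_sinogram`.
#' @param i channel index (1-based).
#' @return a single-channel container of the same kind.
#' @export
extract_channel <- function(x, i) {
  stopifnot(inherits(x, "mc_container"))
  C <- dim(x$values)[1]
  i <- as.integer(i)
  if (i < 1L || i > C) stop("channel index out of range")
  g <- x$geometry
  if (inherits(g, "image_geometry")) {
    g1 <- image_geometry(g$shape, 1L, g$voxel_size,
                         if (!is.null(g$channel_labels)) g$channel_labels[i])
    v <- x$values
    d <- dim(v)
    sl <- array(v[slice.index(v, 1L) == i], dim = c(1L, d[-1]))
    mc_image(g1, sl)
  } else {
    g1 <- g; g1$num_channels <- 1L
    mc_sinogram(g1, x$values[i, , , drop = FALSE])
  }
}

#' Fill one channel of a multichannel container in place
#'
#' Writes `slice` (a single-channel container or a bare array of matching
#' spatial shape) into channel `i` of `x`; other channels are untouched.
#' `extract_channel(fill_channel(x, i, s), i)` recovers `s`.
#'
#' @inheritParams extract_channel
#' @param slice single-channel container or array.
#' @return the updated container.
#' @export
fill_channel <- function(x, i, slice) {
  stopifnot(inherits(x, "mc_container"))
  d <- dim(x$values)
  i <- as.integer(i)
  if (i < 1L || i > d[1]) stop("channel index out of range")
  v <- if (inherits(slice, "mc_container")) slice$values else as.array(slice)
  sd <- dim(v)
  if (length(sd) == length(d) && sd[1] == 1L) sd <- sd[-1]
  if (!identical(as.integer(sd), as.integer(d[-1])))
    stop("slice shape does not match the container's spatial shape")
  idx <- slice.index(x$values, 1L) == i
  x$values[idx] <- as.numeric(v)
  x
}

# ---- block containers -------------------------------------------------

#' Block container
#'
#' Ordered tuple of containers (images, sinograms, or nested blocks) with
#' elementwise algebra, summed inner product and summed squared norm; the
#' product-space element `y = (y1, ..., yn)` used by block operators and
#' separable functions.
#'
#' @param ... containers or nested blocks.
#' @export
block <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], c("mc_container", "block_container")))
    parts <- parts[[1]]
  ok <- vapply(parts, function(p) inherits(p, c("mc_container", "block_container")),
               logical(1))
  if (!all(ok)) stop("block parts must be containers or blocks")
  structure(list(parts = parts), class = "block_container")
}

#' @export
print.block_container <- function(x, ...) {
  cat("block_container of", length(x$parts), "part(s)\n")
  invisible(x)
}

#' Number of parts of a block container
#' @param x a `block_container`.
#' @export
n_parts <- function(x) length(x$parts)

#' Map a function over the raw values of a container
#'
#' Applies `f` to the values array of `x` (recursively over block parts),
#' returning a container of identical structure.  The workhorse behind the
#' elementwise proximal maps.
#'
#' @param x container or block.
#' @param f function on arrays.
#' @export
map_values <- function(x, f) {
  if (inherits(x, "block_container")) {
    block(lapply(x$parts, map_values, f = f))
  } else {
    x$values <- array(f(x$values), dim = dim(x$values))
    x
  }
}

#' Combine two same-structure containers elementwise
#' @param x,y containers of identical structure.
#' @param f binary function on arrays.
#' @export
map2_values <- function(x, y, f) {
  if (inherits(x, "block_container")) {
    if (!inherits(y, "block_container") || n_parts(x) != n_parts(y))
      stop("block structures differ")
    block(Map(map2_values, x$parts, y$parts, MoreArgs = list(f = f)))
  } else {
    if (!identical(dim(x$values), dim(y$values))) stop("container shapes differ")
    x$values <- array(f(x$values, y$values), dim = dim(x$values))
    x
  }
}

#' Inner product of two containers
#'
#' Sum of elementwise products; for blocks, the sum of part-wise inner
#' products.
#' @param x,y containers of identical structure.
#' @export
inner_prod <- function(x, y) {
  if (inherits(x, "block_container")) {
    if (!inherits(y, "block_container") || n_parts(x) != n_parts(y))
      stop("block structures differ")
    sum(vapply(seq_along(x$parts),
               function(i) inner_prod(x$parts[[i]], y$parts[[i]]), numeric(1)))
  } else {
    if (!identical(dim(x$values), dim(y$values))) stop("container shapes differ")
    sum(x$values * y$values)
  }
}

#' Euclidean norm of a container
#' @param x container or block.
#' @export
cnorm <- function(x) sqrt(inner_prod(x, x))

#' Sum of all entries of a container
#' @param x container or block.
#' @export
csum <- function(x) {
  if (inherits(x, "block_container")) sum(vapply(x$parts, csum, numeric(1)))
  else sum(x$values)
}

scalar_or_stop <- function(e) {
  if (!is.numeric(e) || length(e) != 1L)
    stop("container algebra is defined between same-structure containers or with scalars")
  as.numeric(e)
}

#' @export
Ops.mc_container <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop("operation '", .Generic, "' not defined for containers")
  if (missing(e2)) {  # unary
    e1$values <- get(.Generic)(e1$values)
    return(e1)
  }
  f <- get(.Generic)
  if (inherits(e1, "mc_container") && inherits(e2, "mc_container")) {
    map2_values(e1, e2, f)
  } else if (inherits(e1, "mc_container")) {
    s <- scalar_or_stop(e2); map_values(e1, function(v) f(v, s))
  } else {
    s <- scalar_or_stop(e1); map_values(e2, function(v) f(s, v))
  }
}

#' @export
Ops.block_container <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop("operation '", .Generic, "' not defined for blocks")
  if (missing(e2)) return(block(lapply(e1$parts, function(p) get(.Generic)(p))))
  f <- get(.Generic)
  if (inherits(e1, "block_container") && inherits(e2, "block_container")) {
    map2_values(e1, e2, f)
  } else if (inherits(e1, "block_container")) {
    s <- scalar_or_stop(e2)
    block(lapply(e1$parts, function(p) get(.Generic)(p, s)))
  } else {
    s <- scalar_or_stop(e1)
    block(lapply(e2$parts, function(p) get(.Generic)(s, p)))
  }
}

#' Zero container with the same structure as `x`
#' @param x container or block.
#' @export
zero_like <- function(x) map_values(x, function(v) 0 * v)
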