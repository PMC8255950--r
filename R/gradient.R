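# Finite-difference machinery.  Forward differences with Neumann
# (replicate) boundary on every penalized axis; the adjoint is then the
# matching backward-difference divergence with zero boundary flux.  All
# axes use unit step (no voxel-size weighting): the TV-type functionals
# downstream are defined on the index grid.

fdiff <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  if (n == 1L) return(array(0, d))
  idx <- lapply(d, seq_len)
  idx[[axis]] <- c(2:n, n)  # replicate last sample -> last difference 0
  shifted <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  shifted - a
}

# Adjoint of fdiff: (D'y)_j = y_{j-1} [j>1]  -  y_j [j<n]
fdiff_adj <- function(y, axis) {
  d <- dim(y); n <- d[axis]
  if (n == 1L) return(array(0, d))
  idx <- lapply(d, seq_len)
  idx[[axis]] <- c(1L, 1:(n - 1L))
  prev <- do.call(`[`, c(list(y), idx, list(drop = FALSE)))
  prev[slice.index(y, axis) == 1L] <- 0
  res <- prev - y
  last <- slice.index(y, axis) == n
  res[last] <- prev[last]
  res
}

grad_axes <- function(geom, correlation) {
  ns <- length(geom$shape)
  sp <- seq.int(2L, 1L + ns)           # spatial axes of the value array
  switch(correlation,
         space = sp,
         space_channels = c(1L, sp),
         stop("unknown correlation mode '", correlation, "'"))
}

#' Finite-difference gradient operator
#'
#' One forward-difference field per penalized axis, each the same shape as
#' the input; axis order is the channel axis first (in `space_channels`
#' mode) followed by the spatial axes slowest-to-fastest.  The adjoint is
#' the exact negative divergence matching the forward stencil.
#'
#' @param geom the `image_geometry` of the domain.
#' @param correlation `"space"` (spatial differences only, channels are
#'   sites) or `"space_channels"` (channel axis penalized too, same unit
#'   step).
#' @param boundary boundary handling; only `"neumann"` (replicate) is
#'   provided.
#' @return a `linear_map` from images to a block of difference fields.
#' @export
op_gradient <- function(geom, correlation = c("space", "space_channels"),
                        boundary = "neumann") {
  correlation <- match.arg(correlation)
  if (!identical(boundary, "neumann"))
    stop("unknown boundary mode '", boundary, "'")
  if (correlation == "space_channels" && geom$num_channels < 2L)
    stop("space_channels correlation requires num_channels >= 2")
  axes <- grad_axes(geom, correlation)
  dom <- allocate(geom, 0)
  rng <- block(lapply(axes, function(a) dom))
  direct <- function(u) {
    block(lapply(axes, function(a) mc_image(u$geometry, fdiff(u$values, a))))
  }
  adjoint <- function(y) {
    acc <- 0
    for (i in seq_along(axes)) acc <- acc + fdiff_adj(y$parts[[i]]$values, axes[i])
    mc_image(geom, acc)
  }
  K <- linear_map(direct, adjoint, dom, rng,
                  paste0("gradient[", correlation, "]"))
  K
}

#' Gradient of a multichannel image
#'
#' Convenience wrapper returning the block of difference fields directly.
#' @param u a `mc_image`.
#' @inheritParams op_gradient
#' @export
gradient_direct <- function(u, correlation = c("space", "space_channels"),
                            boundary = "neumann") {
  op_apply(op_gradient(u$geometry, match.arg(correlation), boundary), u)
}

#' Adjoint gradient (negative divergence) of a difference-field block
#' @param y block of difference fields as produced by [gradient_direct()].
#' @inheritParams op_gradient
#' @export
gradient_adjoint <- function(y, geom,
                             correlation = c("space", "space_channels"),
                             boundary = "neumann") {
  op_adjoint(op_gradient(geom, match.arg(correlation), boundary), y)
}

#' Symmetrized gradient operator for 2D vector fields
#'
#' Maps a vector field `w = (w_y, w_x)` to the symmetric tensor
#' `E w = (D w + D w') / 2`, stored as 3 planes `(E_yy, E_xx, sqrt(2) E_yx)`.
#' Carrying the factor `sqrt(2)` on the stored off-diagonal plane makes
#' the plain Euclidean norm of the 3-plane output equal the full-tensor
#' Frobenius norm (the doubled off-diagonal accounted for), so the usual
#' mixed l2,1 function applies unchanged and the adjoint stays exactly
#' matched.
#'
#' @param geom the `image_geometry` of each vector component (2 spatial
#'   axes).
#' @return a `linear_map` from 2-blocks to 3-blocks of images.
#' @export
op_sym_gradient <- function(geom) {
  if (length(geom$shape) != 2L)
    stop("symmetrized gradient is implemented for 2 spatial axes")
  ay <- 2L; ax <- 3L
  z <- allocate(geom, 0)
  dom <- block(z, z)
  rng <- block(z, z, z)
  s2 <- 1 / sqrt(2)
  direct <- function(w) {
    if (!inherits(w, "block_container") || n_parts(w) != 2L)
      stop("symmetrized gradient expects one vector component per spatial axis")
    wy <- w$parts[[1]]$values; wx <- w$parts[[2]]$values
    block(mc_image(geom, fdiff(wy, ay)),
          mc_image(geom, fdiff(wx, ax)),
          mc_image(geom, s2 * (fdiff(wy, ax) + fdiff(wx, ay))))
  }
  adjoint <- function(z3) {
    zyy <- z3$parts[[1]]$values; zxx <- z3$parts[[2]]$values
    zyx <- z3$parts[[3]]$values
    block(mc_image(geom, fdiff_adj(zyy, ay) + s2 * fdiff_adj(zyx, ax)),
          mc_image(geom, fdiff_adj(zxx, ax) + s2 * fdiff_adj(zyx, ay)))
  }
  linear_map(direct, adjoint, dom, rng, "sym_gradient")
}

#' Pointwise Euclidean magnitude of a difference-field block
#'
#' Returns the array of per-site magnitudes across block components (the
#' inner `|.|_2` of the mixed l2,1 norm).
#' @param y a block of same-shape containers.
#' @export
block_magnitude <- function(y) {
  acc <- 0
  for (p in y$parts) acc <- acc + p$values^2
  sqrt(acc)
}
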