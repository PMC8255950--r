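# Synthetic phantoms for the three case studies.  Each generator returns
# the ground truth alongside any corrupted data, and is reproducible from
# its arguments and seed.

disc_mask <- function(size, cx, cy, r) {
  # coordinates normalized to [-1, 1]; cx, cy, r in those units
  ax <- seq(-1, 1, length.out = size)
  outer(ax, ax, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

#' Colour (RGB) test phantom with noise and inpainting mask
#'
#' The clean image combines smooth per-channel gradients (sensitive to
#' staircasing) with sharp-edged shapes (a disc and a rectangle).
#' Corruption is either additive Gaussian noise or salt-and-pepper
#' impulses; the inpainting mask removes a repeated-text-like pattern of
#' short horizontal strokes covering a `mask_density` fraction of pixels.
#'
#' @param size image side (>= 32).
#' @param noise `"gaussian"`, `"saltpepper"` or `"none"`.
#' @param noise_level Gaussian standard deviation, or the corrupted-pixel
#'   fraction for salt-and-pepper.
#' @param mask_density fraction of pixels removed by the text mask.
#' @param seed RNG seed.
#' @return list with `clean`, `noisy` (both `mc_image`, 3 channels) and
#'   the logical `mask` (`TRUE` = pixel known).
#' @export
make_colour_phantom <- function(size = 64L, noise = c("gaussian", "saltpepper",
                                                      "none"),
                                noise_level = 0.1, mask_density = 0.15,
                                seed = 1L) {
  noise <- match.arg(noise)
  if (size < 32L) stop("size must be >= 32")
  ax <- seq(0, 1, length.out = size)
  X <- outer(ax, ax, function(y, x) x)
  Y <- outer(ax, ax, function(y, x) y)
  r <- 0.2 + 0.6 * X
  g <- 0.2 + 0.6 * Y
  b <- 0.3 + 0.4 * (X + Y) / 2
  disc <- disc_mask(size, -0.3, -0.3, 0.35)
  rect <- X >= 0.55 & X <= 0.85 & Y >= 0.55 & Y <= 0.85
  r[disc] <- 0.9; g[disc] <- 0.2; b[disc] <- 0.2
  r[rect] <- 0.1; g[rect] <- 0.7; b[rect] <- 0.9
  geom <- image_geometry(c(size, size), 3L)
  vals <- array(0, dim = c(3L, size, size))
  vals[1, , ] <- r; vals[2, , ] <- g; vals[3, , ] <- b
  clean <- mc_image(geom, vals)
  run_with_seed(seed, function() {
    noisy <- clean
    if (noise == "gaussian" && noise_level > 0) {
      noisy <- map_values(clean, function(v)
        v + stats::rnorm(length(v), sd = noise_level))
    } else if (noise == "saltpepper" && noise_level > 0) {
      v <- clean$values
      hit <- stats::runif(length(v)) < noise_level
      v[hit] <- stats::rbinom(sum(hit), 1L, 0.5)
      noisy <- mc_image(geom, v)
    }
    # text-like mask: non-overlapping horizontal 4-pixel stroke slots
    stroke <- 4L
    slots <- size * (size %/% stroke)
    n_miss <- round(mask_density * slots)
    chosen <- sample.int(slots, n_miss)
    mask <- matrix(TRUE, size, size)
    for (s in chosen) {
      row <- (s - 1L) %% size + 1L
      col0 <- ((s - 1L) %/% size) * stroke
      mask[row, col0 + seq_len(stroke)] <- FALSE
    }
    list(clean = clean, noisy = noisy, mask = mask)
  })
}

#' Dynamic contrast-uptake phantom
#'
#' Emulates a gel tube perfused with a contrast agent: a static disc
#' (tube cross-section) containing `n_cavities` circular regions whose
#' intensity rises monotonically over the frames toward an asymptote
#' (an osmosis-like exponential ramp); the background is static.
#'
#' @param frames number of time frames (default 17).
#' @param size spatial side.
#' @param n_cavities number of cavities (default 5).
#' @param diffusion_rate uptake rate per frame; 0 freezes all frames.
#' @param seed kept for interface uniformity (the phantom is
#'   deterministic).
#' @return list with `image` (ground truth `mc_image`, frame-index
#'   channel labels), `tube_mask`, `cavity_masks` (list) and
#'   `cavity_centers` (matrix of row/col indices).
#' @export
make_dynamic_gel_phantom <- function(frames = 17L, size = 64L,
                                     n_cavities = 5L, diffusion_rate = 0.25,
                                     seed = 1L) {
  frames <- as.integer(frames)
  if (frames < 2L) stop("frames must be >= 2")
  tube <- disc_mask(size, 0, 0, 0.85)
  gel <- 0.4
  cav_r <- 0.16
  ring_r <- 0.5
  angles <- 2 * pi * (seq_len(n_cavities) - 1) / n_cavities + 0.3
  centers <- cbind(ring_r * sin(angles), ring_r * cos(angles))  # (y, x)
  cav_masks <- lapply(seq_len(n_cavities), function(k)
    disc_mask(size, centers[k, 1], centers[k, 2], cav_r))
  idx <- function(u) round((u + 1) / 2 * (size - 1)) + 1
  cavity_centers <- cbind(row = idx(centers[, 1]), col = idx(centers[, 2]))
  geom <- image_geometry(c(size, size), frames,
                         channel_labels = seq_len(frames) - 1L)
  vals <- array(0, dim = c(frames, size, size))
  for (t in seq_len(frames)) {
    fr <- matrix(0, size, size)
    fr[tube] <- gel
    ct <- gel + 0.5 * (1 - exp(-diffusion_rate * (t - 1)))
    for (m in cav_masks) fr[m] <- ct
    vals[t, , ] <- fr
  }
  list(image = mc_image(geom, vals), tube_mask = tube,
       cavity_masks = cav_masks, cavity_centers = cavity_centers)
}

#' Hyperspectral phantom with K-edge inclusions
#'
#' A background disc with a smooth, slowly decaying attenuation spectrum
#' and two circular inclusions whose spectra step upward at their
#' characteristic absorption-edge channels.  The default channel axis is
#' 80 bins spanning 75.15 to 93.37 keV, with edges at the channels
#' containing 80.725 keV (gold-like) and 88.005 keV (lead-like).
#'
#' @param channels number of energy bins.
#' @param size spatial side.
#' @param edge_energies absorption-edge energies in keV.
#' @param jumps upward step heights at the edges.
#' @param energy_range keV interval covered by the channel axis.
#' @param seed kept for interface uniformity (deterministic phantom).
#' @return list with `image` (ground truth, keV channel labels),
#'   `energies`, `edge_channels`, `jumps` and ROI masks (`rois$edge1`,
#'   `rois$edge2`, `rois$background`).
#' @export
make_hyperspectral_phantom <- function(channels = 80L, size = 64L,
                                       edge_energies = c(80.725, 88.005),
                                       jumps = c(0.5, 0.4),
                                       energy_range = c(75.15, 93.37),
                                       seed = 1L) {
  channels <- as.integer(channels)
  energies <- seq(energy_range[1], energy_range[2], length.out = channels)
  # bin containing each edge energy (edges between bin centres)
  edge_channels <- vapply(edge_energies, function(e) {
    i <- findInterval(e, energies)
    if (i < 1L || i >= channels) stop("edge energy outside the channel axis")
    i + 1L   # first channel at or above the edge
  }, integer(1))
  rock <- disc_mask(size, 0, 0, 0.85)
  inc1 <- disc_mask(size, -0.35, -0.3, 0.22)
  inc2 <- disc_mask(size, 0.35, 0.3, 0.22)
  bg_only <- rock & !inc1 & !inc2
  geom <- image_geometry(c(size, size), channels, channel_labels = energies)
  vals <- array(0, dim = c(channels, size, size))
  for (e in seq_len(channels)) {
    fr <- matrix(0, size, size)
    fr[rock] <- 0.55 * exp(-0.015 * (e - 1))
    fr[inc1] <- 0.3 + jumps[1] * (e >= edge_channels[1])
    fr[inc2] <- 0.3 + jumps[2] * (e >= edge_channels[2])
    vals[e, , ] <- fr
  }
  list(image = mc_image(geom, vals), energies = energies,
       edge_channels = edge_channels, jumps = jumps,
       rois = list(edge1 = inc1, edge2 = inc2, background = bg_only))
}

#' Forward-simulate an acquisition with optional noise
#'
#' Projects the phantom through the ray-driven forward model, then
#' applies the chosen noise: `"gaussian"` adds i.i.d. noise directly to
#' the attenuation sinogram; `"poisson"` draws photon counts around
#' `I0 * exp(-s)` and converts back through the Lambert-Beer negative
#' logarithm (counts are floored at 1 so the log stays finite).
#'
#' @param img ground-truth `mc_image`.
#' @param acq `acquisition_geometry` with matching channel count.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise standard deviation.
#' @param I0 incident photon count per ray (> 0).
#' @param seed RNG seed.
#' @export
simulate_acquisition <- function(img, acq, noise = c("none", "gaussian",
                                                     "poisson"),
                                 sigma = 0.01, I0 = 1e4, seed = 1L) {
  noise <- match.arg(noise)
  s <- radon_forward(img, acq)
  if (noise == "none") return(s)
  run_with_seed(seed, function() {
    if (noise == "gaussian") {
      if (sigma == 0) return(s)
      map_values(s, function(v) v + stats::rnorm(length(v), sd = sigma))
    } else {
      if (I0 <= 0) stop("I0 must be > 0")
      counts <- map_values(s, function(v)
        pmax(stats::rpois(length(v), I0 * exp(-v)), 1))
      negative_log(counts, flat = I0)
    }
  })
}
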