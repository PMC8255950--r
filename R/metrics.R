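# Image-quality metrics and regularization-parameter grid search.

metric_values <- function(x) {
  if (inherits(x, "mc_container")) x$values else as.array(x)
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 log10(data_range / RMSE)`; `data_range` defaults to the
#' reference's `max - min`.  Identical inputs give `Inf`.
#'
#' @param x,ref containers or arrays of the same shape.
#' @param data_range dynamic range; defaults to `max(ref) - min(ref)`.
#' @export
psnr <- function(x, ref, data_range = NULL) {
  xv <- metric_values(x); rv <- metric_values(ref)
  if (!identical(dim(xv), dim(rv))) stop("shapes must match")
  if (is.null(data_range)) data_range <- max(rv) - min(rv)
  rmse <- sqrt(mean((xv - rv)^2))
  if (rmse == 0) return(Inf)
  20 * log10(data_range / rmse)
}

gauss_kernel <- function(n = 11L, sigma = 1.5) {
  k <- stats::dnorm(seq(-(n - 1) / 2, (n - 1) / 2), sd = sigma)
  k / sum(k)
}

conv_valid <- function(m, k) {
  # separable 'valid' correlation with a symmetric 1D kernel
  a <- apply(m, 2, function(col) stats::convolve(col, k, type = "filter"))
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  t(apply(a, 1, function(row) stats::convolve(row, k, type = "filter")))
}

ssim_plane <- function(x, r, data_range, win, sigma) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  k <- gauss_kernel(win, sigma)
  mu_x <- conv_valid(x, k); mu_r <- conv_valid(r, k)
  xx <- conv_valid(x * x, k); rr <- conv_valid(r * r, k)
  xr <- conv_valid(x * r, k)
  sx <- xx - mu_x^2; sr <- rr - mu_r^2; sxr <- xr - mu_x * mu_r
  num <- (2 * mu_x * mu_r + C1) * (2 * sxr + C2)
  den <- (mu_x^2 + mu_r^2 + C1) * (sx + sr + C2)
  mean(num / den)
}

#' Structural similarity index (SSIM)
#'
#' Standard local-statistics SSIM with a Gaussian window (11 x 11,
#' sigma 1.5 by default, shrunk for small images), computed per channel
#' on the 2D planes and averaged.  Returns a score in `[-1, 1]`;
#' `ssim(ref, ref) = 1`.
#'
#' @param x,ref containers or arrays of identical shape.
#' @param data_range dynamic range; defaults to the reference's.
#' @param win window side (odd).
#' @param sigma Gaussian window standard deviation.
#' @export
ssim <- function(x, ref, data_range = NULL, win = 11L, sigma = 1.5) {
  xv <- metric_values(x); rv <- metric_values(ref)
  if (!identical(dim(xv), dim(rv))) stop("shapes must match")
  if (is.null(data_range)) data_range <- max(rv) - min(rv)
  if (data_range == 0) data_range <- 1
  if (length(dim(xv)) == 2L) { xv <- array(xv, c(1L, dim(xv))); rv <- array(rv, c(1L, dim(rv))) }
  d <- dim(xv)
  win <- min(win, d[length(d)] - 1L, d[length(d) - 1L] - 1L)
  if (win %% 2L == 0L) win <- win - 1L
  if (win < 3L) stop("image too small for SSIM window")
  planes <- if (length(d) == 3L) {
    lapply(seq_len(d[1]), function(c) list(xv[c, , ], rv[c, , ]))
  } else {
    # (C, z, y, x): average over channel-and-z planes
    out <- list()
    for (c in seq_len(d[1])) for (z in seq_len(d[2]))
      out[[length(out) + 1L]] <- list(xv[c, z, , ], rv[c, z, , ])
    out
  }
  mean(vapply(planes, function(p)
    ssim_plane(p[[1]], p[[2]], data_range, win, sigma), numeric(1)))
}

#' Grid search for regularization parameters
#'
#' Runs `runner` at each grid point (over `alphas`, crossed with `betas`
#' when supplied), scores every reconstruction against the ground truth
#' with the chosen criterion and returns the argmax plus the full score
#' table.
#'
#' @param runner function `(alpha)` or `(alpha, beta)` returning a
#'   reconstruction.
#' @param alphas non-empty numeric grid.
#' @param betas optional second grid (e.g. the TGV second-order weight or
#'   a ratio sweep at fixed alpha).
#' @param criterion `"psnr"` or `"ssim"`.
#' @param truth ground-truth container.
#' @return list with `best` (named parameters), `best_score`,
#'   `best_recon` and the score `table`.
#' @export
grid_search_regularization <- function(runner, alphas, betas = NULL,
                                       criterion = c("psnr", "ssim"), truth) {
  criterion <- match.arg(criterion)
  if (!length(alphas)) stop("alpha grid must be non-empty")
  score_fun <- if (criterion == "psnr") psnr else ssim
  rows <- list(); best <- NULL
  grid <- if (is.null(betas)) data.frame(alpha = alphas)
          else expand.grid(alpha = alphas, beta = betas)
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]
    recon <- if (is.null(betas)) runner(a) else runner(a, grid$beta[i])
    sc <- score_fun(recon, truth)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], score = sc)
    if (is.null(best) || sc > best$score)
      best <- list(alpha = a, beta = if (is.null(betas)) NULL else grid$beta[i],
                   score = sc, recon = recon)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(best = best[c("alpha", "beta")], best_score = best$score,
       best_recon = best$recon, table = tab, criterion = criterion)
}

#' Per-channel mean over a region of interest
#'
#' The time-activity curve of dynamic data or the spectral profile of
#' hyperspectral data: the mean reconstructed value inside `roi` for each
#' channel, labelled with the geometry's channel annotation.
#'
#' @param recon a `mc_image`.
#' @param roi logical spatial mask (non-empty).
#' @return data.frame with `channel`, `label`, `value`.
#' @export
time_activity_curve <- function(recon, roi) {
  stopifnot(inherits(recon, "mc_image"))
  roi <- as.array(roi)
  if (!identical(as.integer(dim(roi)), as.integer(dim(recon$values)[-1])))
    stop("roi shape must match the spatial shape")
  if (!any(roi)) stop("roi is empty")
  C <- dim(recon$values)[1]
  vals <- vapply(seq_len(C), function(c) {
    sl <- extract_channel(recon, c)$values
    mean(array(sl, dim = dim(sl)[-1])[roi])
  }, numeric(1))
  labels <- recon$geometry$channel_labels
  data.frame(channel = seq_len(C),
             label = if (is.null(labels)) seq_len(C) else labels,
             value = vals)
}

#' @rdname time_activity_curve
#' @export
spectral_profile <- time_activity_curve
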