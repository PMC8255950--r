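# Container and geometry serialization: per-channel TIFF stacks plus a
# flat key = value plain-text config for geometries.  Channel values are
# min/max-normalized into [0,1] for TIFF storage (the tiff writer clips
# outside that range); the affine scale is kept in the config sidecar so
# round-trips recover physical values.

#' Write a container as a per-channel TIFF stack
#'
#' Each channel is written as one TIFF `<prefix>_ch<i>.tif` (multi-page
#' for 3D spatial grids, one page per z-slice); the geometry and the
#' per-channel value ranges go to `<prefix>_geometry.cfg`.
#'
#' @param x a `mc_image` or `mc_sinogram`.
#' @param prefix path prefix for the output files.
#' @return invisibly, the vector of files written.
#' @export
write_container_tiff <- function(x, prefix) {
  stopifnot(inherits(x, "mc_container"))
  C <- dim(x$values)[1]
  files <- character(0)
  lo <- hi <- numeric(C)
  for (i in seq_len(C)) {
    sl <- extract_channel(x, i)$values
    a <- array(sl, dim = dim(sl)[-1])
    lo[i] <- min(a); hi[i] <- max(a)
    rng <- hi[i] - lo[i]
    a <- if (rng > 0) (a - lo[i]) / rng else array(0, dim = dim(a))
    pages <- if (length(dim(a)) == 3L)
      lapply(seq_len(dim(a)[1]), function(z) a[z, , ]) else a
    f <- sprintf("%s_ch%03d.tif", prefix, i)
    tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    files <- c(files, f)
  }
  cfg <- paste0(prefix, "_geometry.cfg")
  write_geometry_config(x$geometry, cfg,
                        extra = list(channel_min = lo, channel_max = hi))
  invisible(c(files, cfg))
}

#' Read a container written by [write_container_tiff()]
#' @param prefix path prefix used when writing.
#' @export
read_container_tiff <- function(prefix) {
  cfgf <- paste0(prefix, "_geometry.cfg")
  geom <- read_geometry_config(cfgf)
  extra <- read_config_values(cfgf)
  lo <- as.numeric(extra$channel_min); hi <- as.numeric(extra$channel_max)
  x <- allocate(geom, 0)
  C <- geom_dim(geom)[1]
  for (i in seq_len(C)) {
    pg <- tiff::readTIFF(sprintf("%s_ch%03d.tif", prefix, i), all = TRUE)
    a <- if (length(pg) > 1L)
      aperm(simplify2array(pg), c(3, 1, 2)) else pg[[1]]
    a <- a * (hi[i] - lo[i]) + lo[i]
    x <- fill_channel(x, i, array(a, dim = dim(a)))
  }
  x
}

#' Serialize a geometry to a flat key = value config file
#' @param geom an `image_geometry` or `acquisition_geometry`.
#' @param path output file.
#' @param extra optional named list of extra numeric entries to append.
#' @export
write_geometry_config <- function(geom, path, extra = NULL) {
  kv <- function(k, v) sprintf("%s = %s", k,
                               paste(format(v, digits = 17), collapse = " "))
  lines <- if (inherits(geom, "image_geometry")) {
    c(kv("type", "image"), kv("shape", geom$shape),
      kv("num_channels", geom$num_channels), kv("voxel_size", geom$voxel_size),
      if (!is.null(geom$channel_labels)) kv("channel_labels", geom$channel_labels))
  } else {
    c(kv("type", "acquisition"), kv("beam", geom$beam),
      kv("angles", geom$angles), kv("num_bins", geom$num_bins),
      kv("pixel_size", geom$pixel_size), kv("num_channels", geom$num_channels),
      if (!is.null(geom$source_to_origin))
        kv("source_to_origin", geom$source_to_origin),
      if (!is.null(geom$source_to_detector))
        kv("source_to_detector", geom$source_to_detector))
  }
  if (!is.null(extra))
    lines <- c(lines, vapply(names(extra), function(k) kv(k, extra[[k]]),
                             character(1)))
  writeLines(lines, path)
  invisible(path)
}

read_config_values <- function(path) {
  kv <- list()
  for (ln in readLines(path)) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <-
      strsplit(trimws(paste(parts[-1], collapse = "=")), " +")[[1]]
  }
  kv
}

#' Read a geometry config written by [write_geometry_config()]
#' @param path config file.
#' @export
read_geometry_config <- function(path) {
  kv <- read_config_values(path)
  num <- function(k) if (is.null(kv[[k]])) NULL else as.numeric(kv[[k]])
  if (identical(kv$type, "image")) {
    image_geometry(num("shape"), num("num_channels"), num("voxel_size"),
                   num("channel_labels"))
  } else if (identical(kv$type, "acquisition")) {
    acquisition_geometry(kv$beam, num("angles"), num("num_bins"),
                         num("pixel_size"), num("num_channels"),
                         num("source_to_origin"), num("source_to_detector"))
  } else stop("unrecognized geometry config")
}
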