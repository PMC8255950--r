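#' Linear map contract
#'
#' A linear operator between container spaces, defined by its direct and
#' adjoint actions plus zero-filled domain/range templates.  The templates
#' carry the geometry (possibly a block structure) and let generic code
#' draw random probes, run the power method and assemble block operators.
#' The operator norm estimate is cached after first computation.
#'
#' @param direct function: domain container -> range container.
#' @param adjoint function: range container -> domain container.
#' @param domain,range zero containers describing the two spaces.
#' @param name short label used in error messages.
#' @export
linear_map <- function(direct, adjoint, domain, range, name = "linear_map") {
  structure(list(direct = direct, adjoint = adjoint, domain = domain,
                 range = range, name = name, env = new.env(parent = emptyenv())),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat("linear_map <", x$name, ">",
      if (!is.null(x$env$norm)) sprintf(" |K| ~ %.6g", x$env$norm), "\n", sep = "")
  invisible(x)
}

#' Apply a linear map
#' @param K a `linear_map`.
#' @param x domain container.
#' @export
op_apply <- function(K, x) K$direct(x)

#' Apply the adjoint of a linear map
#' @param K a `linear_map`.
#' @param y range container.
#' @export
op_adjoint <- function(K, y) K$adjoint(y)

#' Evaluate a thunk under a temporary RNG seed
#'
#' Runs `fun()` with the RNG seeded to `seed`, restoring the global RNG
#' state afterwards; the deterministic backbone of every stochastic
#' component.
#' @param seed integer seed.
#' @param fun zero-argument function.
#' @export
run_with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Gaussian random container with the structure of a template
#' @param template container or block.
#' @param seed optional seed (global RNG state is preserved).
#' @export
random_like <- function(template, seed = NULL) {
  draw <- function() map_values(template, function(v) stats::rnorm(length(v)))
  if (is.null(seed)) draw() else run_with_seed(seed, draw)
}

#' Operator norm by the power method
#'
#' Iterates `x <- K' K x` from a seeded Gaussian probe; returns the
#' largest-singular-value estimate, stopping when the relative change
#' drops below `tol` or `max_iter` is reached.  A zero operator returns 0.
#' The result is cached on the operator.
#'
#' @param K a `linear_map`.
#' @param max_iter maximum iterations (default 100).
#' @param tol relative-change tolerance (default 1e-5).
#' @param seed RNG seed for the probe (default 42).
#' @export
power_method <- function(K, max_iter = 100L, tol = 1e-5, seed = 42L) {
  x <- random_like(K$domain, seed = seed)
  nx <- cnorm(x)
  if (nx == 0) return(0)
  x <- x * (1 / nx)
  lam <- 0
  for (k in seq_len(max_iter)) {
    z <- op_adjoint(K, op_apply(K, x))
    nz <- cnorm(z)
    if (nz == 0) return(0)
    lam_new <- sqrt(nz)
    x <- z * (1 / nz)
    if (k > 1L && abs(lam_new - lam) < tol * max(lam_new, .Machine$double.eps))
      return(lam_new)
    lam <- lam_new
  }
  lam
}

#' Cached operator norm
#' @inheritParams power_method
#' @export
op_norm <- function(K, max_iter = 100L, tol = 1e-5, seed = 42L) {
  if (is.null(K$env$norm)) K$env$norm <- power_method(K, max_iter, tol, seed)
  K$env$norm
}

#' Identity operator on a container space
#' @param template zero container describing the space.
#' @export
op_identity <- function(template) {
  linear_map(function(x) x, function(y) y, zero_like(template),
             zero_like(template), "identity")
}

#' Zero operator between two container spaces
#' @param domain,range zero containers describing the spaces.
#' @export
op_zero <- function(domain, range) {
  d0 <- zero_like(domain); r0 <- zero_like(range)
  linear_map(function(x) r0, function(y) d0, d0, r0, "zero")
}

#' Scale a linear map by a constant
#' @param K a `linear_map`.
#' @param c scalar.
#' @export
op_scaled <- function(K, c) {
  c <- as.numeric(c)
  linear_map(function(x) op_apply(K, x) * c,
             function(y) op_adjoint(K, y) * c,
             K$domain, K$range, sprintf("%g * %s", c, K$name))
}

#' Compose two linear maps (`A` after `B`)
#' @param A,B `linear_map`s with compatible range/domain.
#' @export
op_compose <- function(A, B) {
  linear_map(function(x) op_apply(A, op_apply(B, x)),
             function(y) op_adjoint(B, op_adjoint(A, y)),
             B$domain, A$range, paste(A$name, "o", B$name))
}

#' Apply a spatial mask to a container
#'
#' Entries where `mask` is `TRUE` pass unchanged; `FALSE` entries become 0.
#' The mask shape must equal one channel's spatial shape; it is broadcast
#' over channels.  As an operator this diagonal map is self-adjoint and
#' idempotent.
#'
#' @param u a `mc_image`.
#' @param mask logical array of the spatial shape.
#' @export
mask_apply <- function(u, mask) {
  stopifnot(inherits(u, "mc_container"))
  d <- dim(u$values)
  if (!identical(as.integer(dim(mask)), as.integer(d[-1])))
    stop("mask shape must equal one channel's spatial shape")
  C <- d[1]
  u$values <- u$values * array(rep(as.numeric(mask), each = C), dim = d)
  u
}

#' Mask operator
#' @param mask logical array of the spatial shape.
#' @param template zero container of the masked space.
#' @export
op_mask <- function(mask, template) {
  z <- zero_like(template)
  M <- linear_map(function(x) mask_apply(x, mask),
                  function(y) mask_apply(y, mask), z, z, "mask")
  M$env$norm <- if (any(mask)) 1 else 0
  M
}

#' Lift a single-channel operator to multichannel data
#'
#' Applies `op` independently per channel; the adjoint is the channelwise
#' lift of `op`'s adjoint and the norm equals `op`'s norm (block-diagonal
#' spectral identity).
#'
#' @param op a `linear_map` whose domain and range are single-channel
#'   containers (not blocks).
#' @param num_channels channel count of the lifted spaces.
#' @export
op_channelwise <- function(op, num_channels) {
  if (inherits(op$domain, "block_container") ||
      inherits(op$range, "block_container"))
    stop("channelwise lift supports container-ranged operators only")
  C <- as.integer(num_channels)
  widen <- function(tmpl) {
    g <- tmpl$geometry
    g$num_channels <- C
    if (inherits(g, "image_geometry")) allocate(g, 0) else allocate(g, 0)
  }
  dom <- widen(op$domain); rng <- widen(op$range)
  per_channel <- function(fun, x, out_tmpl) {
    out <- zero_like(out_tmpl)
    for (i in seq_len(C))
      out <- fill_channel(out, i, fun(extract_channel(x, i)))
    out
  }
  L <- linear_map(function(x) per_channel(op$direct, x, rng),
                  function(y) per_channel(op$adjoint, y, dom),
                  dom, rng, paste0("channelwise(", op$name, ")"))
  if (!is.null(op$env$norm)) L$env$norm <- op$env$norm
  L
}

#' Block operator from a row-wise grid of linear maps
#'
#' `grid` is a list of rows, each a list of `linear_map`s or `NULL`
#' (absent couplings are zero maps).  Output part `r` is the sum over
#' columns `c` of `grid[[r]][[c]]` applied to `x` part `c`; the adjoint
#' transposes the grid and adjoints each cell.
#'
#' @param grid rectangular list-of-rows of `linear_map` / `NULL`.
#' @export
op_block <- function(grid) {
  nr <- length(grid)
  nc <- unique(vapply(grid, length, integer(1)))
  if (length(nc) != 1L) stop("block operator grid must be rectangular")
  dom_parts <- vector("list", nc)
  rng_parts <- vector("list", nr)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    cell <- grid[[r]][[c]]
    if (is.null(cell)) next
    if (!inherits(cell, "linear_map"))
      stop(sprintf("block cell (%d,%d) is not a linear_map", r, c))
    if (is.null(dom_parts[[c]])) dom_parts[[c]] <- zero_like(cell$domain)
    if (is.null(rng_parts[[r]])) rng_parts[[r]] <- zero_like(cell$range)
  }
  if (any(vapply(dom_parts, is.null, logical(1))) ||
      any(vapply(rng_parts, is.null, logical(1))))
    stop("every block row and column needs at least one operator")
  # geometry consistency across cells sharing a row/column
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    cell <- grid[[r]][[c]]
    if (is.null(cell)) next
    same_space <- function(a, b) {
      isTRUE(tryCatch(cnorm(zero_like(a) - b) == 0, error = function(e) FALSE))
    }
    if (!same_space(cell$domain, dom_parts[[c]]) ||
        !same_space(cell$range, rng_parts[[r]]))
      stop(sprintf("inconsistent geometry in block cell (%d,%d)", r, c))
  }
  dom <- block(dom_parts); rng <- block(rng_parts)
  direct <- function(x) {
    if (!inherits(x, "block_container") && nc == 1L) x <- block(list(x))
    out <- lapply(seq_len(nr), function(r) {
      acc <- NULL
      for (c in seq_len(nc)) {
        cell <- grid[[r]][[c]]
        if (is.null(cell)) next
        term <- op_apply(cell, x$parts[[c]])
        acc <- if (is.null(acc)) term else acc + term
      }
      acc
    })
    block(out)
  }
  adjoint <- function(y) {
    if (!inherits(y, "block_container") && nr == 1L) y <- block(list(y))
    out <- lapply(seq_len(nc), function(c) {
      acc <- NULL
      for (r in seq_len(nr)) {
        cell <- grid[[r]][[c]]
        if (is.null(cell)) next
        term <- op_adjoint(cell, y$parts[[r]])
        acc <- if (is.null(acc)) term else acc + term
      }
      acc
    })
    block(out)
  }
  linear_map(direct, adjoint, dom, rng, sprintf("block %dx%d", nr, nc))
}

#' Vertically stack linear maps sharing one domain
#'
#' `x -> (A_1 x, ..., A_n x)` with block range; the adjoint sums the
#' part-wise adjoints.  The one-column special case of [op_block()] with a
#' plain (non-block) domain, convenient for `K = (A; D)` compositions.
#'
#' @param ops list of `linear_map`s with identical domains.
#' @export
op_vstack <- function(ops) {
  stopifnot(length(ops) >= 1L)
  dom <- zero_like(ops[[1]]$domain)
  rng <- block(lapply(ops, function(o) zero_like(o$range)))
  linear_map(
    direct = function(x) block(lapply(ops, function(o) op_apply(o, x))),
    adjoint = function(y) {
      acc <- NULL
      for (i in seq_along(ops)) {
        term <- op_adjoint(ops[[i]], y$parts[[i]])
        acc <- if (is.null(acc)) term else acc + term
      }
      acc
    },
    domain = dom, range = rng,
    name = sprintf("vstack(%s)",
                   paste(vapply(ops, `[[`, character(1), "name"),
                         collapse = "; ")))
}

#' Materialize a linear map as a dense matrix (small spaces only)
#'
#' Builds the matrix column-by-column from unit vectors; intended for
#' desk-scale verification of operators against their functional form.
#'
#' @param K a `linear_map` with plain-container domain and range.
#' @export
op_as_matrix <- function(K) {
  n <- length(flatten_values(K$domain))
  unit <- function(i) {
    e <- flatten_values(K$domain) * 0; e[i] <- 1
    unflatten(K$domain, e)
  }
  cols <- lapply(seq_len(n), function(i) flatten_values(op_apply(K, unit(i))))
  do.call(cbind, cols)
}

unflatten <- function(template, v) {
  if (inherits(template, "block_container")) {
    sizes <- vapply(template$parts, function(p) length(flatten_values(p)),
                    integer(1))
    stops <- cumsum(sizes); starts <- c(1L, stops[-length(stops)] + 1L)
    block(lapply(seq_along(template$parts), function(i)
      unflatten(template$parts[[i]], v[starts[i]:stops[i]])))
  } else {
    template$values <- array(v, dim = dim(template$values))
    template
  }
}

flatten_values <- function(x) {
  if (inherits(x, "block_container"))
    unlist(lapply(x$parts, flatten_values)) else as.numeric(x$values)
}
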