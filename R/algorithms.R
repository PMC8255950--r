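#' Algorithm state
#'
#' Result container for the iterative solvers: final iterate(s), dual
#' variables where applicable, iteration counter, objective trace and the
#' configuration snapshot.  Re-running with an identical configuration
#' (and seed, for the stochastic solvers) reproduces the trace
#' bit-for-bit.
#'
#' @param x final primal iterate.
#' @param trace data.frame with columns `iteration`, `objective`.
#' @param iterations iterations performed.
#' @param config list of configuration values.
#' @param dual optional final dual variable(s).
#' @export
algorithm_state <- function(x, trace, iterations, config = list(), dual = NULL) {
  structure(list(x = x, trace = trace, iterations = iterations,
                 config = config, dual = dual),
            class = "algorithm_state")
}

#' @export
print.algorithm_state <- function(x, ...) {
  cat("algorithm_state:", x$iterations, "iterations")
  if (nrow(x$trace))
    cat(", final objective", signif(x$trace$objective[nrow(x$trace)], 8))
  cat("\n")
  invisible(x)
}

trace_row <- function(trace, k, obj) {
  rbind(trace, data.frame(iteration = k, objective = obj))
}

#' FISTA: accelerated proximal-gradient descent
#'
#' Minimizes `f(x) + g(x)` for differentiable `f` (gradient with
#' Lipschitz constant, or an explicit `step`) and proximable `g`, with
#' the standard momentum extrapolation.
#'
#' @param f smooth `conv_fun` exposing `gradient` (and `lipschitz`, unless
#'   `step` is supplied).
#' @param g proximable `conv_fun`.
#' @param x0 initial container.
#' @param max_iter iterations.
#' @param step step size; defaults to `1 / f$lipschitz`.
#' @param trace_interval objective logging interval (default 10).
#' @export
fista_run <- function(f, g, x0, max_iter = 100L, step = NULL,
                      trace_interval = 10L) {
  if (is.null(step)) {
    if (is.null(f$lipschitz) || f$lipschitz <= 0)
      stop("supply a step size or a function with a Lipschitz constant")
    step <- 1 / f$lipschitz
  }
  x <- x0; y <- x0; t <- 1
  trace <- data.frame(iteration = integer(), objective = numeric())
  for (k in seq_len(max_iter)) {
    x_new <- fn_prox(g, y - fn_gradient(f, y) * step, step)
    t_new <- (1 + sqrt(1 + 4 * t^2)) / 2
    y <- x_new + (x_new - x) * ((t - 1) / t_new)
    x <- x_new; t <- t_new
    if (k %% trace_interval == 0L || k == max_iter)
      trace <- trace_row(trace, k, fn_evaluate(f, x) + fn_evaluate(g, x))
  }
  algorithm_state(x, trace, max_iter, list(step = step, algorithm = "fista"))
}

#' Default PDHG step sizes
#'
#' `sigma = 1`, `tau = 1 / (sigma ||K||^2)`, with the norm estimate
#' inflated by `1 + 1e-3` so the convergence condition
#' `sigma tau ||K||^2 < 1` holds strictly.
#'
#' @param op_norm operator norm estimate (> 0).
#' @export
default_pdhg_stepsizes <- function(op_norm) {
  if (op_norm <= 0) stop("op_norm must be > 0")
  nrm <- op_norm * (1 + 1e-3)
  list(sigma = 1, tau = 1 / nrm^2)
}

#' Primal-dual hybrid gradient (PDHG)
#'
#' Solves `min_x f(K x) + g(x)` through its saddle-point form: conjugate
#' proximal ascent in the dual, proximal descent in the primal and an
#' extrapolation step with parameter `theta = 1`.  The default
#' extrapolates the primal iterate; `extrapolate = "dual"` runs the
#' mirrored form (primal step first, dual extrapolation), which is the
#' deterministic limit of the stochastic variant.  "Implicit" usage is
#' this same loop with `g`'s prox being an inner iterative solve (for
#' example the directional-TV FGP prox).
#'
#' @param K a `linear_map`.
#' @param f `conv_fun` on the range of `K`.
#' @param g `conv_fun` on the domain of `K`.
#' @param x0 initial primal point (defaults to zero).
#' @param sigma,tau step sizes; defaults from [default_pdhg_stepsizes()].
#'   Supplied values violating `sigma tau ||K||^2 < 1` produce a warning,
#'   not an error.
#' @param max_iter iterations.
#' @param theta extrapolation parameter (default 1).
#' @param extrapolate `"primal"` (default) or `"dual"`.
#' @param trace_interval objective logging interval.
#' @export
pdhg_run <- function(K, f, g, x0 = NULL, sigma = NULL, tau = NULL,
                     max_iter = 100L, theta = 1,
                     extrapolate = c("primal", "dual"),
                     trace_interval = 10L) {
  extrapolate <- match.arg(extrapolate)
  nrm <- op_norm(K)
  if (is.null(sigma) || is.null(tau)) {
    st <- default_pdhg_stepsizes(nrm)
    if (is.null(sigma)) sigma <- st$sigma
    if (is.null(tau)) tau <- st$tau
  } else if (sigma * tau * nrm^2 >= 1) {
    warning("sigma * tau * ||K||^2 >= 1: PDHG convergence is not guaranteed")
  }
  if (is.null(x0)) x0 <- zero_like(K$domain)
  x <- x0; xbar <- x0
  y <- zero_like(K$range); ybar <- y
  trace <- data.frame(iteration = integer(), objective = numeric())
  for (k in seq_len(max_iter)) {
    if (extrapolate == "primal") {
      y <- fn_conj_prox(f, y + op_apply(K, xbar) * sigma, sigma)
      x_new <- fn_prox(g, x - op_adjoint(K, y) * tau, tau)
      xbar <- x_new + (x_new - x) * theta
      x <- x_new
    } else {
      x <- fn_prox(g, x - op_adjoint(K, ybar) * tau, tau)
      y_new <- fn_conj_prox(f, y + op_apply(K, x) * sigma, sigma)
      ybar <- y_new + (y_new - y) * theta
      y <- y_new
    }
    if (k %% trace_interval == 0L || k == max_iter)
      trace <- trace_row(trace, k, fn_evaluate(f, op_apply(K, x)) +
                                   fn_evaluate(g, x))
  }
  algorithm_state(x, trace, max_iter,
                  list(sigma = sigma, tau = tau, theta = theta,
                       extrapolate = extrapolate, algorithm = "pdhg"),
                  dual = y)
}

#' Subset sampling patterns for SPDHG
#'
#' With `S` data subsets plus one regularizer term: `"uniform"` gives all
#' `S + 1` terms probability `1 / (S + 1)`; `"balanced"` gives the
#' regularizer probability 0.5 and each data subset `0.5 / S`.  Data
#' subsets come first, the regularizer last.
#'
#' @param kind `"uniform"` or `"balanced"`.
#' @param S number of data subsets (>= 1).
#' @export
sampling_pattern <- function(kind = c("uniform", "balanced"), S) {
  kind <- match.arg(kind)
  S <- as.integer(S)
  if (S <= 0L) stop("S must be >= 1")
  if (kind == "uniform") rep(1 / (S + 1), S + 1)
  else c(rep(0.5 / S, S), 0.5)
}

#' Expected iterations per epoch for SPDHG
#'
#' An epoch is the expected number of iterations needed to process every
#' data subset once.  Balanced sampling selects a data subset with
#' probability 0.5, so an epoch is `2 S` iterations; uniform sampling
#' selects one with probability `S / (S + 1)`, giving `S + 1`.
#'
#' @inheritParams sampling_pattern
#' @export
epoch_iterations <- function(kind = c("uniform", "balanced"), S) {
  kind <- match.arg(kind)
  if (kind == "balanced") 2L * as.integer(S) else as.integer(S) + 1L
}

#' Stochastic PDHG with subset sampling
#'
#' Solves `min_x sum_i f_i(A_i x) + g(x)`.  Each iteration draws one term
#' `i` from the probability vector, updates only that dual block with
#' step `sigma_i`, and takes a primal step with probability-weighted
#' extrapolation.  Step sizes follow the safe rule
#' `sigma_i = gamma / ||A_i||`, `tau = (1 / gamma) min_i(p_i / ||A_i||)`.
#' Deterministic given `seed`; with a single term and `p = 1` the
#' trajectory coincides with dual-extrapolated PDHG at matched steps.
#'
#' @param ops list of `linear_map`s `A_i`.
#' @param fs list of `conv_fun`s `f_i` (same length).
#' @param g proximable `conv_fun` on the shared domain.
#' @param probabilities positive selection probabilities summing to 1.
#' @param x0 initial point (defaults to zero).
#' @param max_iter iterations.
#' @param seed RNG seed (default 42).
#' @param gamma step balance parameter (default 1).
#' @param trace_interval objective logging interval.
#' @export
spdhg_run <- function(ops, fs, g, probabilities, x0 = NULL, max_iter = 100L,
                      seed = 42L, gamma = 1, trace_interval = 10L) {
  n <- length(ops)
  if (length(fs) != n) stop("ops and fs must have the same length")
  p <- as.numeric(probabilities)
  if (length(p) != n || any(p <= 0) || abs(sum(p) - 1) > 1e-10)
    stop("probabilities must be positive and sum to 1")
  norms <- vapply(ops, op_norm, numeric(1))
  sig <- gamma / norms
  tau <- (1 / gamma) * min(p / norms)
  if (is.null(x0)) x0 <- zero_like(ops[[1]]$domain)
  x <- x0
  ys <- lapply(ops, function(A) zero_like(A$range))
  z <- zero_like(x0); zbar <- z
  trace <- data.frame(iteration = integer(), objective = numeric())
  run_with_seed(seed, function() {
    for (k in seq_len(max_iter)) {
      x <<- fn_prox(g, x - zbar * tau, tau)
      i <- sample.int(n, 1L, prob = p)
      y_new <- fn_conj_prox(fs[[i]], ys[[i]] + op_apply(ops[[i]], x) * sig[i],
                            sig[i])
      dz <- op_adjoint(ops[[i]], y_new - ys[[i]])
      ys[[i]] <<- y_new
      z <<- z + dz
      zbar <<- z + dz * (1 / p[i])
      if (k %% trace_interval == 0L || k == max_iter) {
        obj <- fn_evaluate(g, x) +
          sum(vapply(seq_len(n), function(j)
            fn_evaluate(fs[[j]], op_apply(ops[[j]], x)), numeric(1)))
        trace <<- trace_row(trace, k, obj)
      }
    }
  })
  algorithm_state(x, trace, max_iter,
                  list(sigma = sig, tau = tau, probabilities = p,
                       seed = seed, gamma = gamma, algorithm = "spdhg"),
                  dual = ys)
}

#' SIRT: simultaneous iterative reconstruction technique
#'
#' Weighted Landweber iteration
#' `x <- clip(x + C A' R (b - A x))` with `R`, `C` the inverse row- and
#' column-sum diagonal weights of `A`; converges to a weighted
#' least-squares solution, optionally projected onto a box.  Zero
#' rows/columns get weight 0 (those rays/voxels are skipped).
#'
#' @param A a `linear_map`.
#' @param b data container in `A`'s range.
#' @param x0 initial point (defaults to zero).
#' @param max_iter iterations.
#' @param lower,upper optional box bounds.
#' @param trace_interval residual logging interval.
#' @export
sirt_run <- function(A, b, x0 = NULL, max_iter = 100L, lower = -Inf,
                     upper = Inf, trace_interval = 10L) {
  ones_dom <- map_values(zero_like(A$domain), function(v) v + 1)
  ones_rng <- map_values(zero_like(A$range), function(v) v + 1)
  rs <- op_apply(A, ones_dom)     # row sums
  cs <- op_adjoint(A, ones_rng)   # column sums
  if (max(abs(flatten_values(rs))) == 0) stop("all-zero operator")
  inv0 <- function(v) ifelse(v > 0, 1 / v, 0)
  R <- map_values(rs, inv0)
  Cw <- map_values(cs, inv0)
  clip <- function(v) map_values(v, function(a) pmin(pmax(a, lower), upper))
  if (is.null(x0)) x0 <- zero_like(A$domain)
  x <- clip(x0)
  trace <- data.frame(iteration = integer(), objective = numeric())
  for (k in seq_len(max_iter)) {
    r <- b - op_apply(A, x)
    x <- clip(x + Cw * op_adjoint(A, R * r))
    if (k %% trace_interval == 0L || k == max_iter) {
      r <- b - op_apply(A, x)
      trace <- trace_row(trace, k, 0.5 * inner_prod(r, R * r))
    }
  }
  algorithm_state(x, trace, max_iter,
                  list(lower = lower, upper = upper, algorithm = "sirt"))
}

#' Channelwise SIRT with warm starts
#'
#' Runs SIRT channel by channel on a single-channel operator, seeding
#' each channel's iteration with the previous channel's solution — a
#' basic form of channel correlation for multichannel data.
#'
#' @param A_sc single-channel `linear_map` (image -> sinogram).
#' @param b multichannel `mc_sinogram`.
#' @param iters_per_channel SIRT iterations per channel.
#' @param lower,upper box bounds (default nonnegativity).
#' @param warm_start seed each channel with the previous solution
#'   (`TRUE`, default) or start every channel from zero.
#' @return a multichannel `mc_image`.
#' @export
warm_started_channelwise_sirt <- function(A_sc, b, iters_per_channel = 100L,
                                          lower = 0, upper = Inf,
                                          warm_start = TRUE) {
  C <- b$geometry$num_channels
  g <- A_sc$domain$geometry
  gC <- image_geometry(g$shape, C, g$voxel_size)
  out <- allocate(gC, 0)
  prev <- NULL
  for (i in seq_len(C)) {
    bi <- extract_channel(b, i)
    st <- sirt_run(A_sc, bi, x0 = if (warm_start) prev else NULL,
                   max_iter = iters_per_channel, lower = lower, upper = upper)
    prev <- st$x
    out <- fill_channel(out, i, st$x)
  }
  out
}

#' CGLS: conjugate gradients on the normal equations
#'
#' Minimizes `||A x - b||^2` by the conjugate-gradient least-squares
#' iteration, stopping when the normal-equation residual
#' `||A'(A x - b)||` falls below `tol` times its initial value.
#'
#' @param A a `linear_map`.
#' @param b data container.
#' @param x0 initial point (defaults to zero).
#' @param max_iter iterations.
#' @param tol relative residual tolerance.
#' @export
cgls_run <- function(A, b, x0 = NULL, max_iter = 50L, tol = 1e-8) {
  if (is.null(x0)) x0 <- zero_like(A$domain)
  x <- x0
  r <- b - op_apply(A, x)
  s <- op_adjoint(A, r)
  p <- s
  norms0 <- inner_prod(s, s)
  trace <- data.frame(iteration = integer(), objective = numeric())
  if (norms0 == 0)
    return(algorithm_state(x, trace_row(trace, 0L, 0.5 * inner_prod(r, r)),
                           0L, list(algorithm = "cgls")))
  norms_old <- norms0
  for (k in seq_len(max_iter)) {
    q <- op_apply(A, p)
    alpha <- norms_old / inner_prod(q, q)
    x <- x + p * alpha
    r <- r - q * alpha
    s <- op_adjoint(A, r)
    norms_new <- inner_prod(s, s)
    trace <- trace_row(trace, k, 0.5 * inner_prod(r, r))
    if (sqrt(norms_new) < tol * sqrt(norms0)) break
    p <- s + p * (norms_new / norms_old)
    norms_old <- norms_new
  }
  algorithm_state(x, trace, k, list(tol = tol, algorithm = "cgls"))
}
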