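#' Proper convex function contract
#'
#' A function in the variational catalogue: an `evaluate` returning an
#' extended-real scalar (indicator violations return `Inf` rather than
#' raising, so objective traces remain computable), an optional gradient
#' with Lipschitz constant for the smooth members, and a proximal map
#' `prox(x, tau)`.  Conjugate proximal maps are derived generically via
#' the Moreau identity by [fn_conj_prox()].
#'
#' @param evaluate function container -> scalar.
#' @param prox function `(x, tau)` -> container.
#' @param gradient optional function container -> container.
#' @param lipschitz optional Lipschitz constant of `gradient`.
#' @param name label.
#' @export
conv_fun <- function(evaluate, prox, gradient = NULL, lipschitz = NULL,
                     name = "conv_fun") {
  structure(list(evaluate = evaluate, prox = prox, gradient = gradient,
                 lipschitz = lipschitz, name = name,
                 env = new.env(parent = emptyenv())),
            class = "conv_fun")
}

#' @export
print.conv_fun <- function(x, ...) {
  cat("conv_fun <", x$name, ">\n", sep = ""); invisible(x)
}

#' Evaluate a catalogued function
#' @param f a `conv_fun`.
#' @param x container.
#' @export
fn_evaluate <- function(f, x) f$evaluate(x)

#' Proximal map `argmin_v 1/2 ||v - x||^2 + tau f(v)`
#' @param f a `conv_fun`.
#' @param x container.
#' @param tau step (>= 0); `tau = 0` returns `x`.
#' @export
fn_prox <- function(f, x, tau) {
  if (tau < 0) stop("prox step tau must be >= 0")
  if (tau == 0) return(x)
  f$prox(x, tau)
}

#' Gradient of a smooth catalogued function
#' @inheritParams fn_evaluate
#' @export
fn_gradient <- function(f, x) {
  if (is.null(f$gradient)) stop(f$name, " has no gradient")
  f$gradient(x)
}

#' Conjugate proximal map via the Moreau identity
#'
#' `prox_{tau f*}(x) = x - tau * prox_{f / tau}(x / tau)`.
#' @inheritParams fn_prox
#' @export
fn_conj_prox <- function(f, x, tau) {
  if (tau <= 0) stop("conjugate prox requires tau > 0")
  x - fn_prox(f, x * (1 / tau), 1 / tau) * tau
}

sub_off <- function(x, b) if (is.null(b)) x else x - b
add_off <- function(x, b) if (is.null(b)) x else x + b

#' L1 norm `||x - b||_1`
#'
#' Prox is elementwise soft-thresholding around the offset `b`.
#' @param b optional data offset (container), default 0.
#' @export
fn_l1 <- function(b = NULL) {
  conv_fun(
    evaluate = function(x) csum(map_values(sub_off(x, b), abs)),
    prox = function(x, tau) {
      d <- sub_off(x, b)
      add_off(map_values(d, function(v) sign(v) * pmax(abs(v) - tau, 0)), b)
    },
    name = "l1")
}

#' Squared L2 fidelity `1/2 ||x - b||_2^2`
#'
#' Smooth with gradient `x - b` (Lipschitz constant 1); prox
#' `(x + tau b) / (1 + tau)`.
#' @param b optional data offset.
#' @export
fn_l2sq <- function(b = NULL) {
  conv_fun(
    evaluate = function(x) { d <- sub_off(x, b); 0.5 * inner_prod(d, d) },
    prox = function(x, tau) {
      if (is.null(b)) x * (1 / (1 + tau)) else (x + b * tau) * (1 / (1 + tau))
    },
    gradient = function(x) sub_off(x, b),
    lipschitz = 1,
    name = "l2_squared")
}

#' Least-squares fidelity `1/2 ||A x - b||_2^2` through an operator
#'
#' Smooth member used by FISTA/CGLS-style solvers: gradient
#' `A'(A x - b)`, Lipschitz constant `||A||^2`.
#' @param A a `linear_map`.
#' @param b data container in `A`'s range.
#' @export
fn_least_squares <- function(A, b) {
  conv_fun(
    evaluate = function(x) { r <- op_apply(A, x) - b; 0.5 * inner_prod(r, r) },
    prox = function(x, tau) stop("least-squares prox not implemented; use a solver"),
    gradient = function(x) op_adjoint(A, op_apply(A, x) - b),
    lipschitz = op_norm(A)^2,
    name = "least_squares")
}

#' Mixed l2,1 norm of a block
#'
#' Sum over sites of the pointwise Euclidean magnitude across block
#' components; prox is group soft-thresholding (sites with zero magnitude
#' map to zero).
#' @export
fn_l21 <- function() {
  conv_fun(
    evaluate = function(y) sum(block_magnitude(y)),
    prox = function(y, tau) {
      m <- block_magnitude(y)
      shrink <- ifelse(m > 0, pmax(m - tau, 0) / pmax(m, .Machine$double.xmin), 0)
      block(lapply(y$parts, function(p) {
        p$values <- p$values * shrink; p
      }))
    },
    name = "mixed_l21")
}

#' Kullback-Leibler fidelity for Poisson data
#'
#' `sum(x - b + b log(b / x))`, the divergence form with the additive
#' constant making `evaluate(b) = 0` (minimizers of the variational
#' problem are unaffected); `0 log 0` is treated as 0 and the evaluation
#' returns `Inf` where `x <= 0` with `b > 0`.  Prox is the entrywise
#' closed form `(x - tau + sqrt((x - tau)^2 + 4 tau b)) / 2`, always
#' nonnegative.
#' @param b nonnegative data container.
#' @export
fn_kl <- function(b) {
  if (any(flatten_values(b) < 0)) stop("KL data b must be nonnegative")
  bv <- b
  conv_fun(
    evaluate = function(x) {
      xs <- flatten_values(x); bs <- flatten_values(bv)
      if (any(xs < 0) || any(xs == 0 & bs > 0)) return(Inf)
      terms <- xs - bs
      pos <- bs > 0
      terms[pos] <- terms[pos] + bs[pos] * log(bs[pos] / xs[pos])
      sum(terms)
    },
    prox = function(x, tau) {
      map2_values(x, bv, function(xv, bb)
        0.5 * (xv - tau + sqrt((xv - tau)^2 + 4 * tau * bb)))
    },
    name = "kullback_leibler")
}

#' Box indicator with clipping prox
#'
#' `evaluate` is 0 inside `[lower, upper]` and `Inf` outside; the prox
#' clips independently of `tau`.
#' @param lower,upper bounds (scalars), `lower <= upper`.
#' @export
fn_box <- function(lower = 0, upper = Inf) {
  if (any(lower > upper)) stop("box requires lower <= upper")
  conv_fun(
    evaluate = function(x) {
      v <- flatten_values(x)
      if (all(v >= lower - 1e-12) && all(v <= upper + 1e-12)) 0 else Inf
    },
    prox = function(x, tau) map_values(x, function(v) pmin(pmax(v, lower), upper)),
    name = sprintf("box[%g,%g]", lower, upper))
}

#' Zero function (prox is the identity)
#' @export
fn_zero <- function() {
  conv_fun(evaluate = function(x) 0, prox = function(x, tau) x,
           gradient = function(x) zero_like(x), lipschitz = 0, name = "zero")
}

#' Positively scaled function `alpha * f`
#'
#' `prox_{tau (alpha f)} = prox_{(tau alpha) f}`; gradient and Lipschitz
#' constant scale accordingly.
#' @param f a `conv_fun`.
#' @param alpha positive weight.
#' @export
fn_scaled <- function(f, alpha) {
  if (alpha < 0) stop("scale must be >= 0")
  conv_fun(
    evaluate = function(x) alpha * f$evaluate(x),
    prox = function(x, tau) fn_prox(f, x, tau * alpha),
    gradient = if (!is.null(f$gradient)) function(x) f$gradient(x) * alpha,
    lipschitz = if (!is.null(f$lipschitz)) alpha * f$lipschitz,
    name = sprintf("%g * %s", alpha, f$name))
}

#' Separable block function `f(y) = sum_i f_i(y_i)`
#'
#' Evaluate is the sum of parts and the prox applies partwise; arity must
#' match the block it is applied to.
#' @param ... `conv_fun`s, one per block part.
#' @export
fn_block <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1]]) && !inherits(fs[[1]], "conv_fun"))
    fs <- fs[[1]]
  stopifnot(all(vapply(fs, inherits, logical(1), "conv_fun")))
  check <- function(y) {
    if (!inherits(y, "block_container") || n_parts(y) != length(fs))
      stop("block function arity mismatch")
  }
  conv_fun(
    evaluate = function(y) {
      check(y)
      sum(vapply(seq_along(fs),
                 function(i) fs[[i]]$evaluate(y$parts[[i]]), numeric(1)))
    },
    prox = function(y, tau) {
      check(y)
      block(lapply(seq_along(fs), function(i) fn_prox(fs[[i]], y$parts[[i]], tau)))
    },
    name = paste0("block(", paste(vapply(fs, `[[`, character(1), "name"),
                                  collapse = ", "), ")"))
}

#' Split first-order regularizer for channel-plus-space gradients
#'
#' Acts on a gradient block whose first part is the channel (energy or
#' time) difference and whose remaining parts are spatial differences:
#' `beta * ||y_1||_1 + alpha * ||(y_2, ..., y_m)||_{2,1}`.  The prox is
#' separable: scalar soft-thresholding on the channel part and group
#' soft-thresholding across the spatial parts.
#'
#' @param alpha weight of the spatial l2,1 term.
#' @param beta weight of the channel l1 term.
#' @export
fn_split_gradient <- function(alpha, beta) {
  if (alpha < 0 || beta < 0) stop("weights must be >= 0")
  l1 <- fn_scaled(fn_l1(), beta)
  l21 <- fn_scaled(fn_l21(), alpha)
  conv_fun(
    evaluate = function(y) {
      l1$evaluate(y$parts[[1]]) + l21$evaluate(block(y$parts[-1]))
    },
    prox = function(y, tau) {
      sp <- fn_prox(l21, block(y$parts[-1]), tau)
      block(c(list(fn_prox(l1, y$parts[[1]], tau)), sp$parts))
    },
    name = "split_gradient")
}
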