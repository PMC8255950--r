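# Directional total variation: a structure prior that re-weights the
# gradient of the unknown by D_v = I - xi_v xi_v', where xi_v is the
# normalized gradient of a known reference image v.  Gradients parallel
# to the reference's are shrunk by (1 - |xi_v|^2); orthogonal gradients
# pass unchanged, so edges aligned with the reference are favoured.

#' Normalized gradient field of a reference image
#'
#' `xi_v = grad(v) / sqrt(eta^2 + |grad(v)|^2)` with smoothing `eta > 0`,
#' computed with the package's forward-difference Neumann gradient and no
#' pre-smoothing of the reference.  The pointwise magnitude satisfies
#' `0 <= |xi_v| < 1`: zero on locally constant regions, approaching 1 at
#' arbitrarily strong edges, and decreasing everywhere as `eta` grows.
#'
#' @param v single-channel `mc_image` reference.
#' @param eta edge parameter (> 0), in the intensity units of `v`.
#' @return a `directional_weight_field` with components `reference`,
#'   `eta`, `xi` (block of component images) and `magnitude`.
#' @export
normalized_gradient_field <- function(v, eta) {
  stopifnot(inherits(v, "mc_image"))
  if (eta <= 0) stop("eta must be > 0")
  if (v$geometry$num_channels != 1L)
    stop("the reference must be single-channel")
  g <- gradient_direct(v, "space")
  m2 <- block_magnitude(g)^2
  denom <- sqrt(eta^2 + m2)
  xi <- block(lapply(g$parts, function(p) { p$values <- p$values / denom; p }))
  structure(list(reference = v, eta = eta, xi = xi,
                 magnitude = block_magnitude(xi)),
            class = "directional_weight_field")
}

#' @export
print.directional_weight_field <- function(x, ...) {
  cat("directional_weight_field: eta =", x$eta,
      " max |xi| =", signif(max(x$magnitude), 4), "\n")
  invisible(x)
}

#' Apply the directional weight `D_v = I - xi xi'` to a gradient block
#'
#' Pointwise `g - xi (xi . g)`; self-adjoint, with eigenvalues in (0, 1]
#' (a contraction).
#'
#' @param field a `directional_weight_field`.
#' @param g gradient block sharing the field's spatial shape.
#' @export
directional_weight_apply <- function(field, g) {
  xi <- field$xi
  if (n_parts(xi) != n_parts(g)) stop("component count mismatch")
  dims_g <- dim(g$parts[[1]]$values)
  dims_x <- dim(xi$parts[[1]]$values)
  if (!identical(dims_g[-1], dims_x[-1]))
    stop("field and gradient spatial shapes differ")
  C <- dims_g[1]
  bc <- function(a) if (C == dims_x[1]) a else
    array(rep(as.numeric(a), each = C), dim = dims_g)
  dot <- 0
  for (i in seq_len(n_parts(g)))
    dot <- dot + bc(xi$parts[[i]]$values) * g$parts[[i]]$values
  block(lapply(seq_len(n_parts(g)), function(i) {
    p <- g$parts[[i]]
    p$values <- p$values - bc(xi$parts[[i]]$values) * dot
    p
  }))
}

# Weighted gradient W o G as a linear map (W self-adjoint, ||W|| <= 1,
# so ||W G|| <= ||G|| for step-size purposes).
op_weighted_gradient <- function(field, geom) {
  G <- op_gradient(geom, "space")
  W <- linear_map(function(y) directional_weight_apply(field, y),
                  function(y) directional_weight_apply(field, y),
                  zero_like(G$range), zero_like(G$range), "D_v")
  op_compose(W, G)
}

#' Directional TV value `||D_v grad(u)||_{2,1}`
#'
#' Equals `TV(u)` exactly when the reference is constant (`xi = 0`), and
#' is never larger than `TV(u)`.
#' @param u a `mc_image`.
#' @param field a `directional_weight_field`.
#' @export
dtv_value <- function(u, field) {
  g <- gradient_direct(u, "space")
  sum(block_magnitude(directional_weight_apply(field, g)))
}

#' Directional-TV proximal map by FGP
#'
#' Approximately minimizes
#' `1/2 ||v - b||^2 + tau * alpha * dTV(v, reference)` (optionally over
#' `v >= 0`) with the same dual FGP iteration as the TV prox, the gradient
#' replaced by the weighted operator `D_v grad`.
#'
#' @param b a `mc_image`.
#' @param field a `directional_weight_field`.
#' @param alpha regularization weight (>= 0).
#' @param tau prox step (> 0).
#' @param inner_iter FGP iterations (default 100).
#' @param nonneg enforce nonnegativity.
#' @export
dtv_prox_fgp <- function(b, field, alpha, tau = 1, inner_iter = 100L,
                         nonneg = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (!identical(dim(b$values)[-1], dim(field$reference$values)[-1]))
    stop("field and image spatial shapes differ")
  WG <- op_weighted_gradient(field, b$geometry)
  fgp_prox(b, WG, tau * alpha, inner_iter = inner_iter, nonneg = nonneg)
}

#' Directional TV as a catalogued function (for implicit PDHG)
#'
#' @inheritParams dtv_prox_fgp
#' @param geom `image_geometry` of the argument.
#' @export
fn_dtv <- function(field, alpha, geom, inner_iter = 100L, nonneg = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0")
  WG <- op_weighted_gradient(field, geom)
  f <- conv_fun(
    evaluate = function(u) alpha * sum(block_magnitude(op_apply(WG, u))),
    prox = NULL,
    name = sprintf("dtv[alpha=%g, eta=%g]", alpha, field$eta))
  f$prox <- function(b, tau)
    fgp_prox(b, WG, tau * alpha, inner_iter = inner_iter, nonneg = nonneg,
             warm_env = f$env)
  f
}

#' Assemble the TGV inpainting saddle-point problem
#'
#' Builds the triplet for
#' `min_{u,w} ||M u - b||_1 + alpha ||D u - w||_{2,1} + beta ||E w||_{2,1}`:
#' the 3x2 block operator `[[M, O], [D, -I], [O, E]]`, the separable block
#' function `(l1 offset b, alpha l2,1, beta l2,1)` and the zero function
#' `g`.  Feeding the triplet to [pdhg_run()] solves the inpainting
#' problem; with `w = 0` the objective reduces to `||Mu - b||_1 +
#' alpha TV(u)`, so the TGV value never exceeds `alpha TV`.
#'
#' @param b observed (masked, noisy) `mc_image`.
#' @param mask logical spatial array: `TRUE` where data are known.
#' @param alpha first-order weight (> 0).
#' @param beta second-order weight (> 0).
#' @return list with `K`, `f`, `g` and a zero initial point `x0`.
#' @export
tgv_assembly <- function(b, mask, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  geom <- b$geometry
  u0 <- allocate(geom, 0)
  M <- op_mask(mask, u0)
  D <- op_gradient(geom, "space")
  E <- op_sym_gradient(geom)
  Iw <- op_identity(zero_like(D$range))
  K <- op_block(list(list(M, NULL),
                     list(D, op_scaled(Iw, -1)),
                     list(NULL, E)))
  f <- fn_block(fn_l1(b), fn_scaled(fn_l21(), alpha),
                fn_scaled(fn_l21(), beta))
  list(K = K, f = f, g = fn_zero(),
       x0 = block(u0, zero_like(D$range)))
}
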