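ref_edge_image <- function(size = 16) {
  # two-region reference: left half low, right half high
  m <- matrix(0.2, size, size)
  m[, (size / 2 + 1):size] <- 0.8
  mc_image(image_geometry(c(size, size), 1), array(m, c(1, size, size)))
}

test_that("normalized gradient fields are strict contractions", {
  v <- ref_edge_image()
  fld <- normalized_gradient_field(v, 0.1)
  expect_true(all(fld$magnitude < 1))
  expect_true(all(fld$magnitude >= 0))
  # constant reference gives a zero field
  cst <- allocate(image_geometry(c(8, 8), 1), 3)
  expect_equal(max(normalized_gradient_field(cst, 0.5)$magnitude), 0)
  # |xi| decreases pointwise as eta grows
  f1 <- normalized_gradient_field(v, 0.05)
  f2 <- normalized_gradient_field(v, 0.1)
  active <- f1$magnitude > 0
  expect_true(all(f2$magnitude[active] < f1$magnitude[active]))
  # xi -> 0 as eta -> Inf
  expect_lt(max(normalized_gradient_field(v, 1e6)$magnitude), 1e-5)
  expect_error(normalized_gradient_field(v, 0), "eta")
  set.seed(20)
  noisy <- map_values(v, function(a) a + rnorm(length(a), sd = 0.3))
  expect_lt(max(normalized_gradient_field(noisy, 0.005)$magnitude), 1)
})

test_that("directional weight acts as stated on parallel/orthogonal input", {
  v <- ref_edge_image()
  fld <- normalized_gradient_field(v, 0.1)
  g <- gradient_direct(v, "space")          # parallel to xi by construction
  out <- directional_weight_apply(fld, g)
  shrink <- 1 - fld$magnitude^2
  for (i in 1:2)
    expect_equal(out$parts[[i]]$values,
                 g$parts[[i]]$values * shrink, tolerance = 1e-12)
  # orthogonal gradients pass unchanged: rotate (gy, gx) -> (gx, -gy)
  gperp <- block(mc_image(v$geometry, g$parts[[2]]$values),
                 mc_image(v$geometry, -g$parts[[1]]$values))
  outp <- directional_weight_apply(fld, gperp)
  expect_equal(outp$parts[[1]]$values, gperp$parts[[1]]$values,
               tolerance = 1e-12)
  # zero field is the identity
  cst <- allocate(v$geometry, 1)
  fld0 <- normalized_gradient_field(cst, 0.5)
  expect_equal(directional_weight_apply(fld0, g), g)
  # contraction and self-adjointness on random data
  set.seed(21)
  r1 <- block(rand_image(c(16, 16), 1, 31), rand_image(c(16, 16), 1, 32))
  r2 <- block(rand_image(c(16, 16), 1, 33), rand_image(c(16, 16), 1, 34))
  expect_lte(cnorm(directional_weight_apply(fld, r1)), cnorm(r1))
  expect_equal(inner_prod(directional_weight_apply(fld, r1), r2),
               inner_prod(r1, directional_weight_apply(fld, r2)),
               tolerance = 1e-12)
})

test_that("dTV value reduces to TV for constant references and shrinks", {
  u <- rand_image(c(12, 12), 1, seed = 41)
  cst <- allocate(u$geometry, 5)
  fld0 <- normalized_gradient_field(cst, 1)
  expect_equal(dtv_value(u, fld0), tv_value(u, "space"), tolerance = 1e-12)
  v <- ref_edge_image(12)
  fld <- normalized_gradient_field(v, 0.1)
  expect_lt(dtv_value(v, fld), tv_value(v, "space"))
  expect_equal(dtv_value(allocate(u$geometry, 2), fld), 0)
})

test_that("dTV prox matches the TV prox in its degenerate limits", {
  b <- rand_image(c(16, 16), 1, seed = 42)
  g <- b$geometry
  obj_tv <- function(v, alpha) 0.5 * cnorm(v - b)^2 + alpha * tv_value(v, "space")
  # constant reference: exact TV reduction
  fld0 <- normalized_gradient_field(allocate(g, 1), 0.5)
  v1 <- dtv_prox_fgp(b, fld0, 0.3, 1, inner_iter = 300)
  v2 <- fn_prox(fn_tv(0.3, g, "space", inner_iter = 300), b, 1)
  expect_lt(abs(obj_tv(v1, 0.3) - obj_tv(v2, 0.3)), 1e-5)
  # eta -> Inf limit on a structured reference
  fld_inf <- normalized_gradient_field(ref_edge_image(16), 1e6)
  v3 <- dtv_prox_fgp(b, fld_inf, 0.3, 1, inner_iter = 300)
  expect_lt(abs(obj_tv(v3, 0.3) - obj_tv(v2, 0.3)) / abs(obj_tv(v2, 0.3)),
            1e-4)
  expect_equal(dtv_prox_fgp(b, fld0, 0, 1)$values, b$values)
  expect_error(dtv_prox_fgp(b, fld0, -1, 1), "alpha")
})

test_that("an edge-matched reference beats plain TV on a two-region image", {
  size <- 16
  truth <- ref_edge_image(size)
  set.seed(7)
  noisy <- map_values(truth, function(v) v + rnorm(length(v), sd = 0.15))
  fld <- normalized_gradient_field(truth, 0.05)
  alpha <- 0.4
  den_dtv <- dtv_prox_fgp(noisy, fld, alpha, 1, inner_iter = 300)
  den_tv <- fn_prox(fn_tv(alpha, truth$geometry, "space", inner_iter = 300),
                    noisy, 1)
  err <- function(x) cnorm(x - truth)
  expect_lt(err(den_dtv), err(den_tv))
})

test_that("TGV assembly reproduces the saddle-point structure", {
  size <- 8
  b <- rand_image(c(size, size), 3, seed = 50)
  mask <- matrix(TRUE, size, size); mask[3, 4:6] <- FALSE
  asm <- tgv_assembly(b, mask, alpha = 1, beta = 2)
  u <- rand_image(c(size, size), 3, seed = 51)
  y <- op_apply(asm$K, block(u, zero_like(asm$x0$parts[[2]])))
  expect_equal(y$parts[[1]], mask_apply(u, mask))
  expect_equal(y$parts[[2]], gradient_direct(u, "space"))
  expect_equal(cnorm(y$parts[[3]]), 0)
  # w = 0 restriction reproduces l1 + alpha TV (so TGV <= alpha TV)
  expect_equal(fn_evaluate(asm$f, y),
               fn_evaluate(fn_l1(b), mask_apply(u, mask)) +
                 tv_value(u, "space"), tolerance = 1e-10)
  expect_error(tgv_assembly(b, mask, 0, 1), "alpha")
})

test_that("TGV of affine images vanishes at w = Du", {
  size <- 10
  g <- image_geometry(c(size, size), 1)
  aff <- mc_image(g, array(outer(seq_len(size), seq_len(size),
                                 function(i, j) 0.3 * i - 0.7 * j + 2),
                           c(1, size, size)))
  w <- gradient_direct(aff, "space")
  D <- op_gradient(g, "space")
  E <- op_sym_gradient(g)
  # first-order residual Du - w = 0 by construction
  expect_equal(cnorm(op_apply(D, aff) - w), 0)
  # second derivatives of an affine image vanish (interior; Neumann
  # boundary rows are replicated so the whole field is zero except where
  # the stencil leaves the grid)
  ew <- op_apply(E, w)
  interior <- function(a) a[1, 1:(size - 2), 1:(size - 2), drop = FALSE]
  for (p in ew$parts) expect_equal(max(abs(interior(p$values))), 0)
  # constant vector fields are in the kernel of E
  wc <- block(allocate(g, 0.4), allocate(g, -1.2))
  expect_equal(cnorm(op_apply(E, wc)), 0)
})

test_that("TGV denoising avoids staircasing on a noisy ramp", {
  size <- 24
  g <- image_geometry(c(size, size), 1)
  ramp <- mc_image(g, array(outer(seq_len(size), seq_len(size),
                                  function(i, j) (i + j) / (2 * size)),
                            c(1, size, size)))
  set.seed(8)
  noisy <- map_values(ramp, function(v) v + rnorm(length(v), sd = 0.08))
  mask <- matrix(TRUE, size, size)
  # TGV at a ratio favouring second-order smoothness
  asm <- tgv_assembly(noisy, mask, alpha = 0.25, beta = 0.5)
  f2 <- fn_block(fn_l2sq(noisy), fn_scaled(fn_l21(), 0.25),
                 fn_scaled(fn_l21(), 0.5))
  st <- pdhg_run(asm$K, f2, asm$g, x0 = asm$x0, max_iter = 600)
  tgv_mse <- cnorm(st$x$parts[[1]] - ramp)^2
  # TV at its best alpha over a small grid
  tv_mse <- min(vapply(c(0.05, 0.1, 0.2, 0.4), function(a) {
    den <- fn_prox(fn_tv(a, g, "space", inner_iter = 300), noisy, 1)
    cnorm(den - ramp)^2
  }, numeric(1)))
  expect_lt(tgv_mse, tv_mse)
})
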