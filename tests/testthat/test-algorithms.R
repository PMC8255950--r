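scalar_img2 <- function(v, shape = NULL) {
  if (is.null(shape)) shape <- c(1, length(v))
  g <- image_geometry(shape, 1)
  mc_image(g, array(v, c(1, shape)))
}

test_that("FISTA solves lasso instances to their closed form", {
  b <- scalar_img2(c(2, -1, 0.3, 5), c(2, 2))
  f <- fn_l2sq(b)
  st <- fista_run(f, fn_scaled(fn_l1(), 0.5), zero_like(b), max_iter = 300)
  expect_equal(st$x$values, sign(b$values) * pmax(abs(b$values) - 0.5, 0),
               tolerance = 1e-6)
  # g = 0 reduces to accelerated gradient descent on 1/2||x-b||^2
  st0 <- fista_run(f, fn_zero(), zero_like(b), max_iter = 200)
  expect_equal(st0$x$values, b$values, tolerance = 1e-8)
  expect_error(fista_run(conv_fun(function(x) 0, function(x, tau) x),
                         fn_zero(), b), "Lipschitz")
  # convergence: later objective no larger than early objective
  set.seed(61)
  bb <- scalar_img2(rnorm(36), c(6, 6))
  st1 <- fista_run(fn_l2sq(bb), fn_scaled(fn_l1(), 0.3), zero_like(bb),
                   max_iter = 200, trace_interval = 20)
  objs <- st1$trace$objective
  expect_lte(objs[length(objs)], objs[1] + 1e-12)
  expect_true(all(is.finite(objs)))
})

test_that("default PDHG steps satisfy the strict convergence bound", {
  st <- default_pdhg_stepsizes(2)
  expect_equal(st$sigma, 1)
  expect_lt(st$sigma * st$tau * 2^2, 1)
  expect_equal(st$sigma * st$tau * 4, 1 / (1 + 1e-3)^2, tolerance = 1e-12)
  st1 <- default_pdhg_stepsizes(1)
  expect_lt(st1$sigma * st1$tau * 1, 1)
  expect_error(default_pdhg_stepsizes(0), "op_norm")
  # violating user-supplied steps warn but run
  b <- scalar_img2(c(1, 2))
  K <- op_identity(zero_like(b))
  expect_warning(pdhg_run(K, fn_l2sq(b), fn_zero(), sigma = 2, tau = 2,
                          max_iter = 5), "not guaranteed")
})

test_that("PDHG solves lasso and drives zero-data problems to zero", {
  b <- scalar_img2(c(2, -1, 0.3, 5), c(2, 2))
  K <- op_identity(zero_like(b))
  st <- pdhg_run(K, fn_l2sq(b), fn_scaled(fn_l1(), 0.5), max_iter = 500)
  expect_equal(st$x$values, sign(b$values) * pmax(abs(b$values) - 0.5, 0),
               tolerance = 1e-6)
  z <- zero_like(b)
  stz <- pdhg_run(K, fn_l2sq(z), fn_scaled(fn_l1(), 0.1), max_iter = 300)
  expect_lt(cnorm(stz$x), 1e-8)
  expect_true(all(is.finite(st$trace$objective)))
})

test_that("PDHG on the TGV problem approaches its long-run objective", {
  size <- 16
  ph <- make_colour_phantom(size = 32, noise = "saltpepper",
                            noise_level = 0.08, mask_density = 0.1, seed = 3)
  # crop to 16x16 for speed
  crop <- mc_image(image_geometry(c(size, size), 3),
                   ph$noisy$values[, 1:size, 1:size, drop = FALSE])
  mask <- ph$mask[1:size, 1:size]
  asm <- tgv_assembly(mask_apply(crop, mask), mask, 0.4, 0.8)
  st_short <- pdhg_run(asm$K, asm$f, asm$g, x0 = asm$x0, max_iter = 1000,
                       trace_interval = 1000)
  st_long <- pdhg_run(asm$K, asm$f, asm$g, x0 = asm$x0, max_iter = 10000,
                      trace_interval = 10000)
  o_s <- st_short$trace$objective[nrow(st_short$trace)]
  o_l <- st_long$trace$objective[nrow(st_long$trace)]
  expect_lt(abs(o_s - o_l) / abs(o_l), 1e-3)
})

test_that("SPDHG with one subset reproduces dual-extrapolated PDHG", {
  b <- scalar_img2(c(2, -1, 0.3, 5), c(2, 2))
  K <- op_identity(zero_like(b))
  g <- fn_scaled(fn_l1(), 0.5)
  st_s <- spdhg_run(list(K), list(fn_l2sq(b)), g, 1, max_iter = 30, seed = 4)
  st_p <- suppressWarnings(   # steps sit exactly on the bound here
    pdhg_run(K, fn_l2sq(b), g, sigma = st_s$config$sigma,
             tau = st_s$config$tau, max_iter = 30, extrapolate = "dual"))
  expect_identical(st_s$x$values, st_p$x$values)
  # deterministic given the seed
  st_s2 <- spdhg_run(list(K), list(fn_l2sq(b)), g, 1, max_iter = 30, seed = 4)
  expect_identical(st_s$x$values, st_s2$x$values)
  expect_identical(st_s$trace, st_s2$trace)
  expect_error(spdhg_run(list(K), list(fn_l2sq(b)), g, c(0.7, 0.3)),
               "probabilities")
  expect_error(spdhg_run(list(K, K), list(fn_l2sq(b), fn_l2sq(b)), g,
                         c(0.7, 0.2)), "probabilities")
})

test_that("sampling patterns follow the uniform and balanced rules", {
  expect_equal(sampling_pattern("balanced", 10), c(rep(0.05, 10), 0.5))
  expect_equal(sampling_pattern("uniform", 10), rep(1 / 11, 11))
  expect_equal(sampling_pattern("balanced", 1), c(0.5, 0.5))
  expect_error(sampling_pattern("balanced", 0), "S")
  expect_equal(epoch_iterations("balanced", 10), 20L)
  expect_equal(epoch_iterations("uniform", 10), 11L)
})

test_that("balanced sampling empirically selects the regularizer half the time", {
  p <- sampling_pattern("balanced", 10)
  n <- 10000
  draws <- run_with_seed(42L, function() sample.int(11, n, replace = TRUE,
                                                    prob = p))
  freq <- mean(draws == 11)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("SIRT converges to (projected) weighted least squares", {
  b <- scalar_img2(c(1.5, -2, 0.5, 3), c(2, 2))
  I <- op_identity(zero_like(b))
  st <- sirt_run(I, b, max_iter = 50)
  expect_equal(st$x$values, b$values, tolerance = 1e-10)
  # nonnegativity projection clips the negative component
  bneg <- scalar_img2(-1, c(1, 1))
  stn <- sirt_run(op_identity(zero_like(bneg)), bneg, max_iter = 30,
                  lower = 0)
  expect_equal(as.numeric(stn$x$values), 0)
  # dense oracle: solve (A' R A) x = A' R b on a materialized projector
  # (6 angles x 6 bins gives a full-column-rank system, so the weighted
  # least-squares solution is unique)
  ig <- image_geometry(c(4, 4), 1)
  acq <- acquisition_geometry("parallel2D", seq(0, 150, by = 30), 6)
  A <- op_projector(acq, ig)
  bs <- random_like(zero_like(A$range), seed = 71)
  M <- op_as_matrix(A)
  r <- rowSums(M)
  keep <- r > 0                      # zero rows carry weight 0
  M2 <- M[keep, , drop = FALSE]
  R <- diag(1 / r[keep])
  xs <- solve(t(M2) %*% R %*% M2 + 1e-10 * diag(16),
              t(M2) %*% R %*% as.numeric(bs$values)[keep])
  st2 <- sirt_run(A, bs, max_iter = 4000)
  expect_equal(as.numeric(st2$x$values), as.numeric(xs), tolerance = 1e-4)
  expect_error(sirt_run(op_zero(zero_like(b), zero_like(b)), b),
               "all-zero")
})

test_that("warm-started channelwise SIRT reaches residuals faster", {
  ig <- image_geometry(c(8, 8), 1)
  acq1 <- acquisition_geometry("parallel2D", seq(0, 160, by = 20), 8)
  A1 <- op_projector(acq1, ig)
  u <- mc_image(ig, array(aa_disc(8, r = 0.7) * 0.6, c(1, 8, 8)))
  b1 <- op_apply(A1, u)
  # three identical channels
  acq3 <- acq1; acq3$num_channels <- 3L
  b3 <- allocate(acq3, 0)
  for (i in 1:3) b3 <- fill_channel(b3, i, b1)
  res_after <- function(x0) {
    st <- sirt_run(A1, b1, x0 = x0, max_iter = 10, lower = 0)
    cnorm(op_apply(A1, st$x) - b1)
  }
  cold <- res_after(NULL)
  recon <- warm_started_channelwise_sirt(A1, b3, iters_per_channel = 10)
  warm2 <- res_after(extract_channel(recon, 1))
  expect_lt(warm2, cold)
  # channels 2 and 3 of the warm-started run fit better than channel 1
  r1 <- cnorm(op_apply(A1, extract_channel(recon, 1)) - b1)
  r3 <- cnorm(op_apply(A1, extract_channel(recon, 3)) - b1)
  expect_lt(r3, r1)
})

test_that("CGLS solves small systems and keeps residuals monotone", {
  ig <- image_geometry(c(2, 2), 1)
  acq <- acquisition_geometry("parallel2D", c(0, 45, 90, 135), 2)
  A <- op_projector(acq, ig)
  M <- op_as_matrix(A)
  expect_gte(Matrix::rankMatrix(M)[1], 4)   # determined system
  xt <- random_like(zero_like(A$domain), seed = 81)
  b <- op_apply(A, xt)
  st <- cgls_run(A, b, max_iter = 20, tol = 1e-12)
  expect_lt(cnorm(st$x - xt) / cnorm(xt), 1e-8)
  # b = 0 from x0 = 0 returns immediately
  st0 <- cgls_run(A, zero_like(A$range))
  expect_identical(st0$iterations, 0L)
  expect_equal(cnorm(st0$x), 0)
  # 1/2||r||^2 trace is non-increasing
  bb <- random_like(zero_like(A$range), seed = 82)
  st2 <- cgls_run(A, bb, max_iter = 15, tol = 0)
  expect_true(all(diff(st2$trace$objective) <= 1e-10))
})

test_that("PDHG averaged-iterate objective is non-increasing on lasso", {
  set.seed(91)
  b <- scalar_img2(rnorm(25), c(5, 5))
  K <- op_identity(zero_like(b))
  f <- fn_l2sq(b); g <- fn_scaled(fn_l1(), 0.4)
  avg_obj <- function(k) {
    # recompute average over first k iterates
    s <- zero_like(b)
    for (j in 1:k) s <- s + pdhg_run(K, f, g, max_iter = j,
                                     trace_interval = j)$x
    xa <- s * (1 / k)
    fn_evaluate(f, xa) + fn_evaluate(g, xa)
  }
  o <- vapply(c(5, 15, 40), avg_obj, numeric(1))
  expect_true(all(diff(o) <= 1e-9))
})
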