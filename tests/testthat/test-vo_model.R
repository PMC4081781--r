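test_that("vo_energy matches a term-by-term hand computation", {
  p <- vo_params()
  cst <- matrix(3, 4, 4); z <- matrix(0, 4, 4)
  # constant f = u, g = 0: only the eps floor of TV and |g| survives
  expect_equal(vo_energy(cst, cst, z, z, p), 16 * p$eps + 16 * p$mu * p$eps,
               tolerance = 1e-12)
  # u = 0, g = 0: fidelity = lam * ||f||^2 (+ eps floors)
  set.seed(7)
  f <- matrix(runif(16), 4, 4)
  expect_equal(vo_energy(f, z, z, z, p),
               p$lam * sum(f^2) + 16 * p$eps + 16 * p$mu * p$eps,
               tolerance = 1e-12)

  # random instance vs independent summation
  u <- matrix(runif(16), 4, 4)
  g1 <- matrix(runif(16, -1, 1), 4, 4)
  g2 <- matrix(runif(16, -1, 1), 4, 4)
  e_ref <- 0
  for (i in 1:4) for (j in 1:4) {
    ux <- if (j < 4) u[i, j + 1] - u[i, j] else 0
    uy <- if (i < 4) u[i + 1, j] - u[i, j] else 0
    e_ref <- e_ref + sqrt(ux^2 + uy^2 + p$eps^2)
    dg <- g1[i, j] - (if (j > 1) g1[i, j - 1] else 0) +
          g2[i, j] - (if (i > 1) g2[i - 1, j] else 0)
    e_ref <- e_ref + p$lam * (f[i, j] - u[i, j] - dg)^2
    e_ref <- e_ref + p$mu * sqrt(g1[i, j]^2 + g2[i, j]^2 + p$eps^2)
  }
  expect_equal(vo_energy(f, u, g1, g2, p), e_ref, tolerance = 1e-12)
  expect_error(vo_energy(f, u[1:3, ], g1, g2, p), "shape")
})

test_that("a constant image decomposes into itself with zero texture", {
  cst <- matrix(119, 24, 24)
  d <- vo_decompose(cst)
  expect_equal(d$u, cst, tolerance = 1e-6)
  expect_equal(max(abs(d$v)), 0, tolerance = 1e-6)
  expect_equal(structure_layer(cst), cst, tolerance = 1e-6)
})

test_that("cartoon + sinusoidal texture separates into the right layers", {
  cart <- matrix(80, 64, 64); cart[20:45, 10:50] <- 180
  xs <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  tex <- 20 * sin(2 * pi * xs / 4)
  f <- cart + tex
  d <- vo_decompose(f)
  # u moves toward the cartoon and v captures >= 50% of the texture in L2
  expect_lt(sqrt(sum((d$u - cart)^2)), sqrt(sum((f - cart)^2)))
  expect_lt(sqrt(sum((d$v - tex)^2)), 0.5 * sqrt(sum(tex^2)))
})

test_that("texture layer equals the divergence of g and the energy trace is non-increasing", {
  set.seed(8)
  f <- matrix(runif(48 * 48, 0, 255), 48, 48)
  d <- vo_decompose(f)
  expect_equal(max(abs(d$v - vowrhog:::div_backward(d$g1, d$g2))), 0,
               tolerance = 1e-10)
  et <- d$energy_trace
  expect_true(all(diff(et) <= 1e-8 * abs(et[1])))
})

test_that("decomposition is equivariant under gray shifts", {
  img <- ridge_fixture(21, 48)
  # fixed iteration count so both runs take identical update paths
  p <- vo_params(max_outer = 40, tol = 1e-12)
  d0 <- vo_decompose(img, p)
  d5 <- vo_decompose(img + 40, p)
  expect_equal(d5$u, d0$u + 40, tolerance = 1e-8)
  expect_equal(d5$v, d0$v, tolerance = 1e-8)
})

test_that("structure layer has no more total variation than the input", {
  tv <- function(m, eps = 1e-4) {
    h <- nrow(m); w <- ncol(m)
    ux <- cbind(m[, -1] - m[, -w], rep(0, h))
    uy <- rbind(m[-1, ] - m[-h, ], rep(0, w))
    sum(sqrt(ux^2 + uy^2 + eps^2))
  }
  for (sd_ in c(31, 32)) {
    img <- ridge_fixture(sd_, 48)
    expect_lt(tv(structure_layer(img)), tv(img))
  }
})

test_that("the structure layer is more blur-stable than raw pixels and than the texture layer", {
  tpl <- make_identity(77)
  imgs <- lapply(c(1, 6), function(s)
    render_sample(tpl, sample_spec(blur_sigma = s, seed = s)))
  dd <- lapply(imgs, vo_decompose)
  du <- sqrt(sum((dd[[1]]$u - dd[[2]]$u)^2))
  dv <- sqrt(sum((dd[[1]]$v - dd[[2]]$v)^2))
  df <- sqrt(sum((imgs[[1]] - imgs[[2]])^2))
  expect_lt(du, dv)   # structure moves less than texture
  expect_lt(du, df)   # and much less than the raw images

  # mean per-pixel stability of u across a blur pair vs raw
  i2 <- render_sample(tpl, sample_spec(blur_sigma = 2, seed = 2))
  i5 <- render_sample(tpl, sample_spec(blur_sigma = 5, seed = 5))
  expect_lt(mean(abs(structure_layer(i2) - structure_layer(i5))),
            mean(abs(i2 - i5)))
})
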