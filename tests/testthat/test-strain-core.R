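test_that("finite-difference gradients are exact for low-order fields", {
  g <- tagstrain:::coord_grid(16, 16, 1.1)
  # linear displacement u = (0.1 x, 0): gradient 0.1 everywhere
  gr <- finite_difference_gradient(list(ux = 0.1 * g$x,
                                        uy = matrix(0, 16, 16),
                                        pixel_spacing = 1.1))
  expect_equal(gr$duxdx, matrix(0.1, 16, 16), tolerance = 1e-12)
  expect_equal(gr$duydy, matrix(0, 16, 16))
  # constant field: zero gradient
  gc <- finite_difference_gradient(matrix(3.7, 8, 8), spacing = 1.1)
  expect_equal(gc$d_dx, matrix(0, 8, 8))
  # central differences are exact for quadratics in the interior
  gq <- finite_difference_gradient(0.01 * g$x^2, spacing = 1.1)
  interior <- 2:15
  expect_lt(max(abs(gq$d_dx - 0.02 * g$x)[interior, interior]), 1e-9)
  expect_error(finite_difference_gradient(matrix(0, 2, 2), spacing = 1.1),
               "degenerate")
})

test_that("Eulerian strain matches closed forms for stretch and rotation", {
  const_f <- function(a, b, c, d)
    list(f11 = matrix(a, 4, 4), f12 = matrix(b, 4, 4),
         f21 = matrix(c, 4, 4), f22 = matrix(d, 4, 4))
  # F = I -> e = 0
  e0 <- strain_from_forward_gradient(const_f(1, 0, 0, 1))
  expect_equal(e0$exx, matrix(0, 4, 4))
  # proper rotation -> B = I -> e = 0
  th <- pi / 6
  er <- strain_from_forward_gradient(const_f(cos(th), -sin(th),
                                             sin(th), cos(th)))
  expect_lt(max(abs(c(er$exx, er$eyy, er$exy))), 1e-15)
  # pure stretch diag(1.25, 0.8): e = diag((1 - l^-2)/2)
  es <- strain_from_forward_gradient(const_f(1.25, 0, 0, 0.8))
  expect_equal(es$exx[1, 1], 0.18, tolerance = 1e-12)
  expect_equal(es$eyy[1, 1], -0.28125, tolerance = 1e-12)
  # inverse form with G = diag(0.8, 1.25) gives the same strain
  ei <- strain_from_inverse_gradient(const_f(0.8, 0, 0, 1.25))
  expect_equal(ei$exx, es$exx, tolerance = 1e-12)
  expect_equal(ei$eyy, es$eyy, tolerance = 1e-12)
})

test_that("inverse- and forward-gradient routes agree on random tensors", {
  set.seed(101)
  for (k in 1:50) {
    g <- matrix(rnorm(4, sd = 0.3), 2) + diag(2)  # well-conditioned
    gi <- solve(g)
    eg <- strain_from_inverse_gradient(
      list(f11 = matrix(g[1, 1], 2, 3), f12 = matrix(g[1, 2], 2, 3),
           f21 = matrix(g[2, 1], 2, 3), f22 = matrix(g[2, 2], 2, 3)))
    ef <- strain_from_forward_gradient(
      list(f11 = matrix(gi[1, 1], 2, 3), f12 = matrix(gi[1, 2], 2, 3),
           f21 = matrix(gi[2, 1], 2, 3), f22 = matrix(gi[2, 2], 2, 3)))
    expect_lt(max(abs(c(eg$exx - ef$exx, eg$eyy - ef$eyy,
                        eg$exy - ef$exy))), 1e-10)
  }
})

test_that("non-positive determinants are masked, not thrown", {
  f <- list(f11 = matrix(c(1, -1), 1, 2), f12 = matrix(0, 1, 2),
            f21 = matrix(0, 1, 2), f22 = matrix(1, 1, 2))
  # grid is tiny but strain_from_forward_gradient has no grid constraint
  e <- strain_from_forward_gradient(f)
  expect_true(e$mask[1, 1])
  expect_false(e$mask[1, 2])
  expect_true(is.na(e$exx[1, 2]))
})

test_that("principal decomposition matches an independent eigen oracle", {
  # already-diagonal and pure-shear closed forms
  ed <- tagstrain:::new_strain_field(matrix(0.18, 2, 2),
                                     matrix(-0.28125, 2, 2),
                                     matrix(0, 2, 2))
  pd <- principal_decomposition(ed)
  expect_equal(pd$eps_p1[1, 1], 0.18)
  expect_equal(pd$eps_p2[1, 1], -0.28125)
  expect_equal(c(pd$n1x[1, 1], pd$n1y[1, 1]), c(1, 0))
  esh <- tagstrain:::new_strain_field(matrix(0, 2, 2), matrix(0, 2, 2),
                                      matrix(0.1, 2, 2))
  psh <- principal_decomposition(esh)
  expect_equal(psh$eps_p1[1, 1], 0.1)
  expect_equal(psh$eps_p2[1, 1], -0.1)
  expect_equal(c(psh$n1x[1, 1], psh$n1y[1, 1]), rep(sqrt(2) / 2, 2),
               tolerance = 1e-12)
  # 1000 random symmetric tensors against base eigen()
  set.seed(7)
  a <- rnorm(1000); b <- rnorm(1000); c <- rnorm(1000)
  e <- tagstrain:::new_strain_field(matrix(a, 40), matrix(b, 40),
                                    matrix(c, 40))
  p <- principal_decomposition(e)
  for (k in seq(1, 1000, by = 37)) {
    ev <- eigen(matrix(c(a[k], c[k], c[k], b[k]), 2), symmetric = TRUE)
    expect_lt(abs(p$eps_p1[k] - ev$values[1]), 1e-12)
    expect_lt(abs(p$eps_p2[k] - ev$values[2]), 1e-12)
  }
  # invariants: orthogonal unit directions, tensor reconstruction
  expect_lt(max(abs(p$n1x * p$n2x + p$n1y * p$n2y)), 1e-6)
  expect_lt(max(abs(p$n1x^2 + p$n1y^2 - 1)), 1e-12)
  recon_xx <- p$eps_p1 * p$n1x^2 + p$eps_p2 * p$n2x^2
  recon_xy <- p$eps_p1 * p$n1x * p$n1y + p$eps_p2 * p$n2x * p$n2y
  expect_lt(max(abs(recon_xx - e$exx)), 1e-6)
  expect_lt(max(abs(recon_xy - e$exy)), 1e-6)
})

test_that("principal strains are rotation invariant", {
  set.seed(8)
  for (k in 1:20) {
    a <- rnorm(1); b <- rnorm(1); cc <- rnorm(1); th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    m <- matrix(c(a, cc, cc, b), 2)
    mr <- R %*% m %*% t(R)
    p1 <- principal_decomposition(tagstrain:::new_strain_field(
      matrix(a, 1, 3), matrix(b, 1, 3), matrix(cc, 1, 3)))
    p2 <- principal_decomposition(tagstrain:::new_strain_field(
      matrix(mr[1, 1], 1, 3), matrix(mr[2, 2], 1, 3),
      matrix(mr[1, 2], 1, 3)))
    expect_lt(abs(p1$eps_p1[1] - p2$eps_p1[1]), 1e-10)
    expect_lt(abs(p1$eps_p2[1] - p2$eps_p2[1]), 1e-10)
  }
})

test_that("rigid motion yields near-zero strain through the numeric path", {
  g <- tagstrain:::coord_grid(64, 64, 1.1)
  th <- 0.15
  cx <- 35; cy <- 35
  X <- cx + cos(th) * (g$x - cx) + sin(th) * (g$y - cy) + 2.3
  Y <- cy - sin(th) * (g$x - cx) + cos(th) * (g$y - cy) - 1.1
  gX <- finite_difference_gradient(X, 1.1)
  gY <- finite_difference_gradient(Y, 1.1)
  p <- principal_decomposition(strain_from_inverse_gradient(
    list(f11 = gX$d_dx, f12 = gX$d_dy, f21 = gY$d_dx, f22 = gY$d_dy)))
  expect_lt(max(abs(p$eps_p1)), 1e-3)
  expect_lt(max(abs(p$eps_p2)), 1e-3)
})

test_that("tidy() returns one row per valid pixel", {
  p <- principal_decomposition(tagstrain:::new_strain_field(
    matrix(0.1, 3, 3), matrix(-0.1, 3, 3), matrix(0, 3, 3)))
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  expect_named(td, c("row", "col", "eps_p1", "eps_p2"))
})
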