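test_that("gradient_map follows the [-1,0,1] mask and the documented axis convention", {
  cst <- matrix(9, 8, 8)
  expect_equal(max(gradient_map(cst)$mag), 0)

  ramp <- matrix(seq_len(8), 8, 8, byrow = TRUE)  # f(i,j) = j
  om <- gradient_map(ramp)
  expect_equal(om$mag[4, 4], 2)   # central difference of a linear ramp
  expect_equal(om$ang[4, 4], 0)   # +x = increasing column

  vramp <- matrix(-(seq_len(8)), 8, 8)            # decreasing in i
  om2 <- gradient_map(vramp)
  expect_equal(om2$ang[4, 4], 3 * pi / 2)         # -y direction
  expect_error(gradient_map(matrix(1, 2, 2)), "at least")
})

test_that("hog matches a pixel-by-pixel accumulation oracle", {
  cst <- matrix(5, 8, 8)
  expect_equal(hog(gradient_map(cst), 12), rep(0, 12))

  ramp <- matrix(seq_len(8), 8, 8, byrow = TRUE)
  h4 <- hog(gradient_map(ramp), 4)
  expect_equal(h4, c(1, 0, 0, 0))

  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(runif(36, 0, 255), 6, 6)
    om <- gradient_map(img)
    expect_equal(hog(om, 12), oracle_hog(om$mag, om$ang, 12),
                 tolerance = 1e-12)
  }
  expect_error(hog(gradient_map(ramp), 1), "at least 2")
})

test_that("rigo_at is zero on constants, radially consistent on a cone, and 90-degree equivariant", {
  cst <- matrix(4, 16, 16)
  expect_equal(max(rigo_at(cst, c(8, 8))[, "mag"]), 0)

  # radially symmetric cone centered on the pixel: equal local angles
  y <- matrix(seq_len(17), 17, 17); x <- t(y)
  cone <- 200 - 8 * sqrt((x - 9)^2 + (y - 9)^2)
  pr <- rigo_at(cone, c(9, 9))
  expect_true(all(pr[, "mag"] > 0))
  expect_lt(max(pr[, "ang"]) - min(pr[, "ang"]), 1e-9)

  # exact 90-degree grid rotation: same multiset of (mag, ang) pairs
  img <- ridge_fixture(41, 17)
  p1 <- rigo_at(img, c(9, 9))
  p2 <- rigo_at(rot90_grid(img), c(9, 9))
  o1 <- order(p1[, 1], p1[, 2]); o2 <- order(p2[, 1], p2[, 2])
  expect_equal(p1[o1, ], p2[o2, ], tolerance = 1e-6)

  expect_error(rigo_at(cst, c(2, 8)), "border")
})

test_that("rigo_at agrees with an independently coded geometry oracle", {
  set.seed(42)
  img <- matrix(runif(20 * 20, 0, 255), 20, 20)
  for (px in list(c(5, 5), c(10, 13), c(16, 4))) {
    got <- rigo_at(img, px)
    ref <- oracle_rigo_pairs(img, px[1], px[2])
    expect_equal(unname(got[, "mag"]), ref[, 1], tolerance = 1e-10)
    expect_equal(unname(got[, "ang"]), ref[, 2], tolerance = 1e-10)
  }
})

test_that("rihog equals the brute-force double-loop oracle and is 90-degree invariant", {
  set.seed(43)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  expect_equal(rihog(img), oracle_rihog(img), tolerance = 1e-10)

  expect_equal(rihog(matrix(7, 16, 16)), rep(0, 12))

  tex <- ridge_fixture(44, 32)
  for (k in 1:3) {
    expect_lt(sum(abs(rihog(tex) - rihog(Reduce(function(m, .) rot90_grid(m),
                                                seq_len(k), tex)))), 1e-6)
  }
})

test_that("rihog is more robust than hog to small continuous rotations", {
  # compare on a central crop so rotation only re-orients the texture and
  # does not swap content in and out at the borders
  crop <- function(m) m[13:68, 13:68]
  wins <- 0L
  for (sd_ in 1:8) {
    img <- band_limited_fixture(sd_ + 50)
    rot <- rotate_image(img, 8)
    d_hog <- sum(abs(hog(gradient_map(crop(img))) -
                     hog(gradient_map(crop(rot)))))
    d_ri <- sum(abs(rihog(crop(img)) - rihog(crop(rot))))
    expect_lt(d_ri, 0.1)
    if (d_ri < d_hog) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("rhog concatenates independent per-block RIHOGs row-major", {
  set.seed(45)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  fv <- rhog(img, b = 16, n_bins = 12)
  expect_length(fv, 48)
  expect_equal(attr(fv, "weighted"), FALSE)

  # segment j equals rihog of block j
  pb <- partition_blocks(img, 16)
  for (j in 1:4)
    expect_equal(fv[((j - 1) * 12 + 1):(j * 12)],
                 rihog(pb$blocks[[j]]$pixels), tolerance = 1e-12)

  # swapping two blocks of the input swaps the corresponding segments
  img2 <- img
  img2[1:16, 1:16] <- img[1:16, 17:32]
  img2[1:16, 17:32] <- img[1:16, 1:16]
  fv2 <- rhog(img2, 16, 12)
  expect_equal(fv2[1:12], fv[13:24], tolerance = 1e-12)
  expect_equal(fv2[13:24], fv[1:12], tolerance = 1e-12)
  expect_equal(fv2[25:48], fv[25:48], tolerance = 1e-12)

  expect_equal(max(abs(rhog(matrix(3, 32, 32), 16))), 0)
})

test_that("wrhog is rhog scaled blockwise by the fractal dimension", {
  img <- ridge_fixture(46, 32)
  fv_r <- rhog(img, 16)
  fv_w <- wrhog(img, 16)
  pb <- partition_blocks(img, 16)
  for (j in 1:4) {
    D <- fractal_dimension(pb$blocks[[j]]$pixels)
    seg <- ((j - 1) * 12 + 1):(j * 12)
    expect_equal(fv_w[seg], D * fv_r[seg], tolerance = 1e-10)
  }
  # single-block image: wrhog = D * rihog elementwise
  blk <- img[1:16, 1:16]
  expect_equal(as.numeric(wrhog(blk, 16)),
               fractal_dimension(blk) * rihog(blk), tolerance = 1e-10)
  # constant image: zero regardless of weights
  expect_equal(max(abs(wrhog(matrix(8, 32, 32), 16))), 0)
})

test_that("feature length bookkeeping is floor(H/b)*floor(W/b)*N", {
  img <- matrix(runif(130 * 70, 0, 255), 130, 70)
  expect_length(rhog(img, 16, 12), 8 * 4 * 12)
  expect_length(block_hog(img, 16, 10), 8 * 4 * 10)
  expect_length(wrhog(img[1:64, 1:64], 32, 6), 2 * 2 * 6)
})

test_that("histograms are L1-normalized or identically zero", {
  set.seed(47)
  for (rep in 1:10) {
    img <- matrix(runif(24 * 24, 0, 255), 24, 24)
    expect_equal(sum(rihog(img)), 1, tolerance = 1e-12)
    expect_equal(sum(hog(gradient_map(img))), 1, tolerance = 1e-12)
    segs <- matrix(rhog(img, 12, 6), nrow = 6)
    expect_equal(colSums(segs), rep(1, 4), tolerance = 1e-12)
  }
})
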