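test_that("ncc reproduces hand values and affine invariance", {
  a <- c(1, 2, 3, 4)
  expect_equal(ncc(a, a), 1, tolerance = 1e-12)
  expect_equal(ncc(a, 3 * a + 2), 1, tolerance = 1e-12)
  expect_equal(ncc(a, -2 * a + 1), -1, tolerance = 1e-12)

  b <- c(1, 3, 2, 4)
  # hand evaluation with population standard deviations
  da <- a - mean(a); db <- b - mean(b)
  ref <- sum(da * db) / (4 * sqrt(mean(da^2)) * sqrt(mean(db^2)))
  expect_equal(ncc(a, b), ref, tolerance = 1e-12)
  expect_equal(ref, 0.8, tolerance = 1e-12)  # frozen from the hand formula
  expect_equal(ncc(a, b), ncc(b, a))

  expect_warning(z <- ncc(a, rep(2, 4)), "zero-variance")
  expect_equal(z, 0)
  expect_error(ncc(a, 1:3), "mismatch")
})

test_that("ncc_matrix agrees with pairwise ncc", {
  set.seed(61)
  A <- matrix(runif(12), 3, 4)
  B <- matrix(runif(8), 2, 4)
  S <- vowrhog:::ncc_matrix(A, B)
  for (i in 1:3) for (j in 1:2)
    expect_equal(S[i, j], ncc(A[i, ], B[j, ]), tolerance = 1e-12)
})

test_that("match_counts reproduces the all-vs-all protocol arithmetic", {
  mc <- match_counts(386, 10, 10)
  expect_equal(mc$total, 14899600)
  expect_equal(mc$genuine, 38600)
  expect_equal(mc$imposter, 14899600 - 38600)

  expect_equal(unlist(match_counts(1, 1, 1)), c(total = 1, genuine = 1,
                                                imposter = 0))
  expect_equal(unlist(match_counts(3, 2, 2)), c(total = 36, genuine = 12,
                                                imposter = 24))

  # explicit pair enumeration for all small protocols
  for (np in 1:4) for (ng in 1:3) for (npr in 1:3) {
    gal <- rep(seq_len(np), each = ng)
    pro <- rep(seq_len(np), each = npr)
    pairs <- expand.grid(p = seq_along(pro), g = seq_along(gal))
    gen <- sum(pro[pairs$p] == gal[pairs$g])
    mc <- match_counts(np, ng, npr)
    expect_equal(mc$total, nrow(pairs))
    expect_equal(mc$genuine, gen)
  }
})

test_that("far_frr matches exhaustive counting at every threshold", {
  s <- score_set(c(0.9, 0.8), c(0.1, 0.2))
  cv <- far_frr(s, thresholds = 0.5)
  expect_equal(cv$far, 0); expect_equal(cv$frr, 0)

  cv2 <- far_frr(s, thresholds = -5)
  expect_equal(cv2$far, 1); expect_equal(cv2$frr, 0)

  set.seed(62)
  g <- round(runif(40, -1, 1), 2); im <- round(runif(60, -1, 1), 2)
  sc <- score_set(g, im)
  cv3 <- far_frr(sc)
  for (k in seq_along(cv3$thresholds)) {
    ref <- oracle_far_frr_at(g, im, cv3$thresholds[k])
    expect_equal(cv3$far[k], unname(ref["far"]), tolerance = 1e-12)
    expect_equal(cv3$frr[k], unname(ref["frr"]), tolerance = 1e-12)
  }
  # monotone with opposite senses as the threshold decreases
  expect_true(all(diff(cv3$far) >= 0))
  expect_true(all(diff(cv3$frr) <= 0))
})

test_that("eer agrees with the sweep oracle and handles degenerate sets", {
  # separable
  e1 <- eer(far_frr(score_set(c(0.9, 0.8), c(0.1, 0.2))))
  expect_equal(e1$eer, 0)

  # identical sets: EER 1/2 by symmetry
  same <- c(0.1, 0.4, 0.7)
  e2 <- eer(far_frr(score_set(same, same)))
  expect_equal(e2$eer, 0.5, tolerance = 1e-12)

  e3 <- eer(far_frr(score_set(c(0.8, 0.6, 0.4), c(0.5, 0.3, 0.1))))
  expect_equal(e3$eer, oracle_eer(c(0.8, 0.6, 0.4), c(0.5, 0.3, 0.1)),
               tolerance = 1e-12)

  set.seed(63)
  for (rep in 1:20) {
    g <- runif(15, 0, 1); im <- runif(25, -0.5, 0.8)
    got <- eer(far_frr(score_set(g, im)))
    expect_equal(got$eer, oracle_eer(g, im), tolerance = 1e-10)
    # bounded by the bracketing FAR/FRR operating points
    cv <- far_frr(score_set(g, im))
    expect_gte(got$eer + 1e-12, 0)
    expect_lte(got$eer - 1e-12, max(cv$far))
  }
})

test_that("decidability matches the formula and is scale invariant", {
  s <- score_set(c(1, 1, 1, 0.9), c(0, 0, 0, 0.1))
  g <- s$genuine; im <- s$imposter
  ref <- abs(mean(g) - mean(im)) /
    sqrt((mean((g - mean(g))^2) + mean((im - mean(im))^2)) / 2)
  expect_equal(decidability(s), ref, tolerance = 1e-12)

  expect_equal(decidability(score_set(c(0.3, 0.5), c(0.5, 0.3))), 0)

  cc <- 0.4
  expect_equal(decidability(score_set(cc * g, cc * im)), decidability(s),
               tolerance = 1e-12)
  expect_error(decidability(score_set(c(0.2, 0.2), c(0.2, 0.2))),
               "degenerate")
})
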