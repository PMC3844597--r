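test_that("Ki values convert to engagement strengths on the pKi scale", {
  tab <- data.frame(drug = c("a", "a", "b"),
                    mechanism = c("DAT", "SERT", "DAT"),
                    Ki_nM = c(1, NA, 100))
  B <- kiToBinding(tab)
  expect_equal(B["a", "DAT"], 4.0)        # pKi 9 minus floor 5
  expect_equal(B["a", "SERT"], 0)         # missing = no affinity
  expect_equal(B["b", "DAT"], 2.0)
  expect_gt(B["a", "DAT"], B["b", "DAT"]) # tighter binding, larger B
  expect_error(kiToBinding(data.frame(drug = "a", mechanism = "m",
                                      Ki_nM = -5)), "positive")
  expect_error(kiToBinding(data.frame(x = 1)), "columns")
})

test_that("sensitivity fitting solves the bilinear model", {
  withr::with_seed(51, {
    A_true <- matrix(rnorm(13 * 60), 13, 60,
                     dimnames = list(paste0("m", 1:13),
                                     sprintf("p%03d", 1:60)))
    B <- matrix(runif(14 * 13, 0.5, 4), 14, 13,
                dimnames = list(paste0("d", 1:14), paste0("m", 1:13)))
  })
  # identity binding returns the responses themselves
  Bi <- diag(13)
  dimnames(Bi) <- list(paste0("m", 1:13), paste0("m", 1:13))
  A_id <- fitSensitivity(t(A_true), Bi)
  expect_equal(unname(A_id), unname(A_true), tolerance = 1e-10)

  # noiseless full-rank recovery to 1e-8
  E <- t(A_true) %*% t(B)                        # transcript x drug
  A_hat <- fitSensitivity(E, B)
  expect_lt(max(abs(A_hat - A_true)), 1e-8)
  # reconstruction reproduces E exactly when E lies in B's column span
  expect_lt(max(abs(t(A_hat) %*% t(B) - E)), 1e-8)

  expect_error(fitSensitivity(E[, 1:5], B), "match")
  expect_error(fitSensitivity(E, B * 0), "all zero")
})

test_that("rank-deficient binding yields the minimum-norm solution", {
  B <- rbind(d1 = c(1, 1), d2 = c(2, 2))        # rank 1
  E <- cbind(d1 = c(3), d2 = c(6))
  rownames(E) <- "p1"
  A <- fitSensitivity(E, B)
  # any solution satisfies a1 + a2 = 3; minimum norm is (1.5, 1.5)
  expect_equal(unname(A[, 1]), c(1.5, 1.5), tolerance = 1e-10)
})

test_that("reduction keeps the top-k most sensitive transcripts per
           mechanism", {
  A <- rbind(m1 = c(9, 0, 0, 1), m2 = c(0, -8, 0, 2))
  colnames(A) <- paste0("p", 1:4)
  red <- reduceSensitive(A, topK = 2)
  expect_equal(red$transcripts, c("p1", "p2", "p4"))
  expect_equal(red$unionSize, 3)

  # disjoint per-mechanism top lists: union is mechanisms x k
  A2 <- matrix(0, 3, 9, dimnames = list(paste0("m", 1:3), paste0("p", 1:9)))
  A2[1, 1:3] <- 5; A2[2, 4:6] <- 5; A2[3, 7:9] <- 5
  expect_equal(reduceSensitive(A2, 3)$unionSize, 9)

  # identical sensitivity profiles: full overlap
  A3 <- matrix(rep(c(3, 2, 1, 0), each = 3), 3, 4, byrow = FALSE)
  A3 <- rbind(m1 = c(3, 2, 1, 0), m2 = c(3, 2, 1, 0))
  colnames(A3) <- paste0("p", 1:4)
  expect_equal(reduceSensitive(A3, 2)$unionSize, 2)
  expect_error(reduceSensitive(A3, 0), "positive")
  expect_error(reduceSensitive(A3, 9), "exceeds")
})

test_that("mechanism prediction is exact, scale-equivariant, and
           self-consistent", {
  withr::with_seed(61, {
    A <- matrix(rnorm(5 * 40), 5, 40,
                dimnames = list(paste0("m", 1:5), sprintf("p%03d", 1:40)))
    B <- matrix(runif(8 * 5, 0.2, 3), 8, 5,
                dimnames = list(paste0("d", 1:8), paste0("m", 1:5)))
  })
  # zero signature: zero activation
  z <- predictMechanisms(setNames(rep(0, 40), colnames(A)), A)
  expect_equal(unname(z$activation), rep(0, 5))
  expect_equal(z$residual, 0)

  # noiseless training drug recovers its own binding row
  E <- t(A) %*% t(B)
  for (d in c(1, 5)) {
    pred <- predictMechanisms(setNames(E[, d], rownames(E)), A)
    expect_equal(unname(pred$activation), unname(B[d, ]), tolerance = 1e-6)
    expect_lt(pred$residual, 1e-8)
  }

  # scaling the signature scales the activation
  e1 <- setNames(E[, 2], rownames(E))
  p1 <- predictMechanisms(e1, A)$activation
  p3 <- predictMechanisms(3 * e1, A)$activation
  expect_equal(p3, 3 * p1, tolerance = 1e-10)
  expect_error(predictMechanisms(e1[1:10], A), "lacks")
})

test_that("leave-one-out validation is exact without noise and flags
           unpredictable drugs", {
  withr::with_seed(71, {
    A <- matrix(rnorm(4 * 120), 4, 120,
                dimnames = list(paste0("m", 1:4), sprintf("p%03d", 1:120)))
    B <- matrix(runif(10 * 4, 0.5, 3), 10, 4,
                dimnames = list(paste0("d", 1:10), paste0("m", 1:4)))
  })
  E <- t(A) %*% t(B)
  loo <- looValidate(E, B, topK = 60)
  expect_true(all(loo$predictable))
  expect_equal(loo$cosine, rep(1, 10), tolerance = 1e-6)

  # a drug sharing no mechanism with the others is unpredictable
  B2 <- cbind(B, m5 = 0)
  B2[1, ] <- c(0, 0, 0, 0, 2)                    # only drug 1 uses m5
  withr::with_seed(72, A2 <- rbind(A, m5 = rnorm(120)))
  E2 <- t(A2) %*% t(B2)
  loo2 <- looValidate(E2, B2, topK = 60)
  expect_false(loo2$predictable[1])
  expect_true(is.na(loo2$cosine[1]))
  expect_error(looValidate(E[, 1:2], B[1:2, ]), ">= 3 drugs")
})
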