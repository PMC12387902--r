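test_that("forward pass matches the worked two-unit example", {
  # s = (1, 1), C = 1, all weights zero:
  # h = s, net_i = h_1 + h_2 = 2, o = h * (1 - 2) = -1
  f <- autoCMForward(c(1, 1), v = c(0, 0), w = matrix(0, 2, 2), C = 1)
  expect_equal(f$h, c(1, 1), tolerance = 1e-12)
  expect_equal(f$net, c(2, 2), tolerance = 1e-12)
  expect_equal(f$o, c(-1, -1), tolerance = 1e-12)
})

test_that("single learning step matches hand-computed scalars to 1e-12", {
  s <- c(0.5, 1); v <- c(0.1, 0.2)
  w <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)  # w[1,2] = 0.3, w[2,1] = 0.2
  C <- 1.25; lam <- 0.1
  # hand computation, written out scalar by scalar
  h1 <- 0.5 * (1 - 0.1 / 1.25)                      # 0.46
  h2 <- 1.0 * (1 - 0.2 / 1.25)                      # 0.84
  net1 <- h1 * (1 - 0.1 / 1.25) + h2 * (1 - 0.3 / 1.25)
  net2 <- h1 * (1 - 0.2 / 1.25) + h2 * (1 - 0.4 / 1.25)
  o1 <- h1 * (1 - net1 / 1.25)
  o2 <- h2 * (1 - net2 / 1.25)
  f <- autoCMForward(s, v, w, C)
  expect_equal(f$h, c(h1, h2), tolerance = 1e-12)
  expect_equal(f$net, c(net1, net2), tolerance = 1e-12)
  expect_equal(f$o, c(o1, o2), tolerance = 1e-12)
  up <- autoCMUpdate(s, v, w, C, lam)
  expect_equal(up$v[1], 0.1 + 0.1 * (0.5 - h1) * (1 - 0.1 / 1.25),
               tolerance = 1e-12)
  expect_equal(up$v[2], 0.2 + 0.1 * (1.0 - h2) * (1 - 0.2 / 1.25),
               tolerance = 1e-12)
  expect_equal(up$w[1, 1], 0.1 + 0.1 * (h1 - o1) * (1 - 0.1 / 1.25) * h1,
               tolerance = 1e-12)
  expect_equal(up$w[1, 2], 0.3 + 0.1 * (h1 - o1) * (1 - 0.3 / 1.25) * h2,
               tolerance = 1e-12)
  expect_equal(up$w[2, 1], 0.2 + 0.1 * (h2 - o2) * (1 - 0.2 / 1.25) * h1,
               tolerance = 1e-12)
  expect_equal(up$w[2, 2], 0.4 + 0.1 * (h2 - o2) * (1 - 0.4 / 1.25) * h2,
               tolerance = 1e-12)
})

test_that("compiled epoch loop equals the reference R step exactly", {
  set.seed(31)
  n <- 5; N <- 4
  m <- matrix(runif(n * N), n, N)
  cfg <- autoCMConfig()
  v <- rep(cfg$eps0, N)
  w <- matrix(cfg$eps0, N, N)
  ord <- c(3L, 1L, 5L, 2L, 4L)
  res <- RorschachMap:::.autocm_epochs(
    m, v, w, cfg$C, cfg$lambda, matrix(ord, nrow = 1), rep(TRUE, N), 1e-300)
  for (r in ord) {
    st <- autoCMUpdate(m[r, ], v, w, cfg$C, cfg$lambda)
    v <- st$v; w <- st$w
  }
  expect_equal(res$v, v, tolerance = 1e-14)
  expect_equal(unname(res$w), unname(w), tolerance = 1e-14)
})

test_that("mono-weights are monotonically non-decreasing and bounded by C", {
  set.seed(32)
  s <- runif(4)
  C <- 1.25
  v <- rep(0.01, 4)
  w <- matrix(0.01, 4, 4)
  prev <- v
  for (k in 1:200) {
    st <- autoCMUpdate(s, v, w, C, lambda = 0.05)
    v <- st$v; w <- st$w
    expect_true(all(v >= prev - 1e-15))
    expect_true(all(v <= C))
    prev <- v
  }
})

test_that("training on the 47-variable fixture saturates and reproduces", {
  co <- scaleCohort(appendGroupIndicators(rorschachFixture()))
  fit <- trainAutoCM(co)
  expect_true(isConverged(fit))
  cfg <- fit@config
  expect_true(all(cfg$C - fit@v[fit@active] <= cfg$tol * cfg$C))
  fit2 <- trainAutoCM(co)
  expect_identical(fit@w, fit2@w)
  expect_identical(trainingEpochs(fit), trainingEpochs(fit2))
})

test_that("training is robust to the record presentation order", {
  co <- scaleCohort(appendGroupIndicators(rorschachFixture()))
  a1 <- associationMatrix(trainAutoCM(co, autoCMConfig(seed = 1)))@.Data
  a2 <- associationMatrix(trainAutoCM(co, autoCMConfig(seed = 2)))@.Data
  expect_lt(max(abs(a1 - a2)), 0.01)
})

test_that("association matrix is a valid similarity matrix", {
  co <- scaleCohort(toyCohort())
  a <- associationMatrix(suppressWarnings(trainAutoCM(co)))
  m <- a@.Data
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
  expect_identical(rownames(m), variableNames(co))
})

test_that("all-zero input is flagged as non-converged without training", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  expect_warning(fit <- trainAutoCM(m), "did not reach")
  expect_false(isConverged(fit))
  expect_equal(trainingEpochs(fit), 0L)
  expect_equal(unname(fit@v), rep(fit@config$eps0, 3))
})

test_that("input domain is enforced", {
  expect_error(trainAutoCM(matrix(2, 3, 3)), "\\[0, 1\\]")
  expect_error(trainAutoCM(matrix(0.5, 3, 1)), "two variables")
  expect_error(autoCMConfig(C = 0))
  expect_error(autoCMConfig(eps0 = 2))
})

test_that("epoch cap returns a warning and a usable partial fit", {
  co <- scaleCohort(toyCohort())
  expect_warning(fit <- trainAutoCM(co, autoCMConfig(maxEpochs = 3)),
                 "3 epochs")
  expect_false(isConverged(fit))
  expect_equal(trainingEpochs(fit), 3L)
  expect_s4_class(associationMatrix(fit), "AssociationMatrix")
})
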