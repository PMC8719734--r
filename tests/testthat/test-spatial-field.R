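test_that("queen adjacency has the right neighbour counts", {
  W <- build_adjacency(3, 3)
  expect_true(isSymmetric(W))
  expect_true(all(diag(W) == 0))
  counts <- colSums(W)
  expect_equal(counts[5], 8, ignore_attr = TRUE)         # centre
  expect_equal(counts[c(1, 3, 7, 9)], rep(3, 4), ignore_attr = TRUE)
  expect_equal(counts[c(2, 4, 6, 8)], rep(5, 4), ignore_attr = TRUE)
  # handshake identity
  expect_equal(sum(counts), 2 * sum(W[upper.tri(W)]))
  W4 <- build_adjacency(4, 5)
  expect_equal(sort(unique(colSums(W4))), c(3, 5, 8))
  expect_error(build_adjacency(1, 5), "2 x 2")
})

test_that("CAR conditionals average neighbours with variance tau/w", {
  f <- spatial_field(3, 3)
  eps <- rep(0.2, 9)
  cc <- car_conditional(5, eps, tau = 0.4, f)
  expect_equal(cc$mean, 0.2)
  expect_equal(cc$variance, 0.4 / 8)
  cc1 <- car_conditional(1, eps, tau = 0.4, f)
  expect_equal(cc1$variance, 0.4 / 3)
})

test_that("joint pairwise-difference prior is consistent with conditionals", {
  # changing eps_i by delta changes the (unconstrained) quadratic form
  # exactly as the conditional Gaussian log-density predicts
  f <- spatial_field(3, 3)
  set.seed(9)
  for (rep in 1:5) {
    eps <- rnorm(9, 0, 0.3)
    i <- sample(9, 1)
    tau <- runif(1, 0.05, 1)
    x1 <- rnorm(1, 0, 0.3)
    W <- f$W
    S <- function(e) clockfield:::.car_quadform(e, W)
    e2 <- eps; e2[i] <- x1
    joint_diff <- -(S(e2) - S(eps)) / (2 * tau)
    cm <- sum(W[i, ] * eps) / f$neighbor_counts[i]
    cv <- tau / f$neighbor_counts[i]
    cond_diff <- dnorm(x1, cm, sqrt(cv), log = TRUE) -
      dnorm(eps[i], cm, sqrt(cv), log = TRUE)
    expect_equal(joint_diff, cond_diff, tolerance = 1e-10)
  }
})

test_that("car_logprior scales with tau and peaks at zero field", {
  f <- spatial_field(2, 2)
  eps <- c(0.1, -0.1, 0.05, -0.05)
  lp1 <- car_logprior(eps, 0.2, f)
  lp2 <- car_logprior(eps, 0.4, f)
  L <- 4
  quad1 <- lp1 + (L - 1) / 2 * log(0.2)
  quad2 <- lp2 + (L - 1) / 2 * log(0.4)
  expect_equal(quad2, quad1 / 2, tolerance = 1e-10)
  expect_gt(car_logprior(rep(0, 4), 0.2, f), lp1)
  expect_error(car_logprior(c(0.3, 0, 0, 0), 0.2, f), "sum to zero")
  # gradient of the quadratic form matches finite differences
  W <- f$W
  g_an <- 2 * (diag(colSums(W)) - W) %*% eps
  g_fd <- vapply(1:4, function(i) {
    h <- 1e-6; e1 <- eps; e1[i] <- e1[i] + h
    (clockfield:::.car_quadform(e1, W) -
       clockfield:::.car_quadform(eps, W)) / h
  }, numeric(1))
  expect_equal(as.numeric(g_an), g_fd, tolerance = 1e-4)
})

test_that("multiplicative effects preserve the geometric mean", {
  theta <- c(R = 50, K = 100, n = 5, dmean = 9, dsd = 4)
  eps <- matrix(rnorm(20, 0, 0.1), 4, 5)
  eps <- sweep(eps, 2, colMeans(eps))
  out <- apply_random_effects(theta, eps)
  expect_equal(out[2, ], theta * exp(eps[2, ]), ignore_attr = TRUE)
  expect_equal(exp(colMeans(log(out))), theta, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply_random_effects(theta, matrix(0, 4, 5))[1, ], theta,
               ignore_attr = TRUE)
  expect_equal(apply_random_effects(theta, matrix(log(2), 4, 5))[1, ],
               2 * theta, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constrained CAR draws are centred and spatially coherent", {
  f <- spatial_field(6, 6)
  set.seed(17)
  nb <- which(f$W == 1, arr.ind = TRUE)
  cors <- replicate(100, {
    e <- sample_car_field(f, tau = 0.05)
    c(sum(e), cor(e[nb[, 1]], e[nb[, 2]]))
  })
  expect_lt(max(abs(cors[1, ])), 1e-10)
  expect_gt(mean(cors[2, ]), 0)   # positive neighbour correlation
})
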