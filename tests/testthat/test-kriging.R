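test_that("empirical variogram matches hand-computed toy values", {
  # stations at 0, 1, 2 m with values 0, 1, 2: pairs (1,1) at lag 1, (2) at lag 2
  emp <- empirical_variogram(c(0, 1, 2), c(0, 0, 0), c(0, 1, 2),
                             n_bins = 2, max_lag = 2.5)
  expect_equal(emp$gamma, c(0.5, 2.0))
  expect_equal(emp$n_pairs, c(2L, 1L))
  # constant field
  flat <- empirical_variogram(runif(10), runif(10), rep(3, 10), n_bins = 4)
  expect_equal(flat$gamma, rep(0, nrow(flat)))
  # scale equivariance: doubling values quadruples gamma
  set.seed(31)
  x <- runif(20); y <- runif(20); v <- rnorm(20)
  e1 <- empirical_variogram(x, y, v, n_bins = 5)
  e2 <- empirical_variogram(x, y, 2 * v, n_bins = 5)
  expect_equal(e2$gamma, 4 * e1$gamma)
  expect_error(empirical_variogram(rep(1, 5), rep(2, 5), rnorm(5)), "co-located")
})

test_that("variogram fit recovers exact and simulated spherical parameters", {
  lags <- seq(1, 20, length.out = 10)
  gamma <- variogram_gamma(lags, "spherical", 0.2, 1, 8)
  emp <- structure(data.frame(lag = lags, gamma = gamma, n_pairs = 50L),
                   class = c("empirical_variogram", "data.frame"))
  vm <- fit_variogram(emp, "spherical")
  expect_equal(vm$nugget, 0.2, tolerance = 1e-3)
  expect_equal(vm$psill, 1, tolerance = 1e-3)
  expect_equal(vm$range_param, 8, tolerance = 1e-3)

  # simulation-recovery: Gaussian field with known spherical structure
  set.seed(32)
  n <- 200
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  D <- as.matrix(dist(cbind(x, y)))
  Cov <- 1.1 - matrix(variogram_gamma(as.vector(D), "spherical", 0.1, 1, 10), n, n)
  diag(Cov) <- 1.1
  z <- as.vector(MASS::mvrnorm(1, rep(0, n), Cov))
  fit <- fit_variogram(empirical_variogram(x, y, z, n_bins = 15, max_lag = 30),
                       "spherical")
  expect_lt(abs(fit$range_param - 10) / 10, 0.25)
  expect_lt(abs((fit$nugget + fit$psill) - 1.1) / 1.1, 0.25)
})

test_that("white noise fits as an essentially flat (pure nugget) variogram", {
  set.seed(33)
  n <- 150
  x <- runif(n, 0, 40); y <- runif(n, 0, 40)
  z <- rnorm(n)
  vm <- fit_variogram(empirical_variogram(x, y, z, n_bins = 12), "spherical")
  lags <- seq(1, 20, length.out = 50)
  g <- variogram_gamma(lags, vm$model, vm$nugget, vm$psill, vm$range_param)
  # fitted curve varies by < 15% of the sill: no spurious spatial structure
  expect_lt(diff(range(g)), 0.15 * max(g))
})

test_that("ordinary kriging is exact at stations and honours unbiasedness", {
  set.seed(34)
  st <- data.frame(x = runif(12, 0, 10), y = runif(12, 0, 10))
  v <- rnorm(12)
  vm <- structure(list(model = "spherical", nugget = 0, psill = 1,
                       range_param = 6), class = "variogram_model")
  at_st <- ordinary_krige(vm, st, v, st)
  expect_equal(at_st$pred, v, tolerance = 1e-10)
  expect_equal(at_st$krige_var, rep(0, 12), tolerance = 1e-8)

  tg <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 10))
  kr <- ordinary_krige(vm, st, v, tg)
  expect_equal(unname(rowSums(attr(kr, "weights"))), rep(1, 20),
               tolerance = 1e-10)
  # all-equal station values -> constant prediction regardless of model
  expect_equal(ordinary_krige(vm, st, rep(7, 12), tg)$pred, rep(7, 20))
  # translation invariance
  st2 <- st; st2$x <- st2$x + 100; st2$y <- st2$y - 50
  tg2 <- tg; tg2$x <- tg2$x + 100; tg2$y <- tg2$y - 50
  expect_equal(ordinary_krige(vm, st2, v, tg2)$pred, kr$pred, tolerance = 1e-9)
})

test_that("3-station kriging system matches a longhand linear solve", {
  st <- data.frame(x = c(0, 4, 0), y = c(0, 0, 3))
  v <- c(1, 2, 4)
  vm <- structure(list(model = "exponential", nugget = 0.1, psill = 0.9,
                       range_param = 5), class = "variogram_model")
  tg <- data.frame(x = 1, y = 1)
  gam <- function(h) ifelse(h == 0, 0, 0.1 + 0.9 * (1 - exp(-3 * h / 5)))
  sill <- 1
  d <- as.matrix(dist(st)); C <- sill - gam(d); diag(C) <- sill
  K <- rbind(cbind(C, 1), c(1, 1, 1, 0))
  d0 <- sqrt((st$x - 1)^2 + (st$y - 1)^2)
  sol <- solve(K, c(sill - gam(d0), 1))
  want_pred <- sum(sol[1:3] * v)
  want_var <- sill - sum(sol[1:3] * (sill - gam(d0))) - sol[4]
  kr <- ordinary_krige(vm, st, v, tg)
  expect_equal(kr$pred, unname(want_pred), tolerance = 1e-10)
  expect_equal(kr$krige_var, unname(want_var), tolerance = 1e-10)
})

test_that("kriging variance grows with distance from the stations", {
  st <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, 1))
  vm <- structure(list(model = "spherical", nugget = 0, psill = 1,
                       range_param = 4), class = "variogram_model")
  tg <- data.frame(x = c(0.5, 2, 4, 8), y = 0.3)
  kv <- ordinary_krige(vm, st, c(1, 2, 3), tg)$krige_var
  expect_true(all(diff(kv) >= -1e-10))
  # duplicate stations are averaged, not fatal
  st2 <- rbind(st, st[1, ])
  expect_silent(ordinary_krige(vm, st2, c(1, 2, 3, 5), tg))
})
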