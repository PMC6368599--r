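# Bayesian engine: posterior correctness, interval utilities, diagnostics

test_that("coefficient gradient matches numerical differentiation for both prior group types", {
  set.seed(2)
  U <- 3; N <- 8; K <- 5
  X <- cbind(matrix(as.numeric(diag(4)[rep(1:4, 2), ]), 8, 4),
             sex = rep(0:1, 4))
  y <- matrix(rpois(U * N, 20), U, N)
  lo <- matrix(log(100), U, N)
  mask <- matrix(1, U, N)
  gf <- c(0L, 0L, 0L, 0L, 1L)      # first four columns: compound group
  gtype <- c(1L, 0L)
  cs <- c(1, 3, 0.5)               # (within, between) then regular
  for (rep in 1:3) {
    th <- rnorm(U * K + 3, 0, 0.5)
    r <- comotraj:::.hb_logp_grad(y, lo, mask, X, gf, gtype, cs, th)
    num <- vapply(seq_len(U * K), function(i) {
      e <- 1e-5; tp <- th; tm <- th
      tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
      (comotraj:::.hb_logp_grad(y, lo, mask, X, gf, gtype, cs, tp)$logp_coef -
         comotraj:::.hb_logp_grad(y, lo, mask, X, gf, gtype, cs, tm)$logp_coef) /
        (2 * e)
    }, 1)
    expect_lt(max(abs(num - r$grad_coef)), 1e-5)
  }
})

test_that("posterior matches the conjugate Gamma-Poisson closed form", {
  # y = 100, offset = 1000: likelihood-dominated, closed-form posterior
  # for the rate is ~ Gamma(100 + eps, 1000); the weak half-normal prior
  # perturbs the median by far less than Monte Carlo error
  meds <- vapply(1:20, function(s) {
    fit <- hbpois(y = 100, offset = 1000, X = cbind(intercept = 1),
                  coef_groups = 1, group_scales = 3,
                  control = sampler_control(n_warmup = 200, n_draws = 250,
                                            seed = s))
    median(exp(coef_draws(fit)[, 1, 1]))
  }, 1)
  oracle <- qgamma(0.5, 100, 1000)
  mcse <- sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) - oracle), 2 * mcse + 1e-3)
  # each individual run is close too
  expect_true(all(abs(meds - oracle) < 0.008))
})

test_that("no-events limit concentrates the rate near zero", {
  fit <- hbpois(y = 0, offset = 1e6, X = cbind(intercept = 1),
                coef_groups = 1, group_scales = 3,
                control = sampler_control(n_warmup = 300, n_draws = 500,
                                          seed = 7))
  h <- hdi(exp(coef_draws(fit)[, 1, 1]))
  expect_lt(h$upper, 10 / 1e6)
})

test_that("rate posterior is invariant to doubling counts and offsets jointly within MC error", {
  X <- cbind(intercept = 1)
  f1 <- hbpois(y = 50, offset = 500, X = X, coef_groups = 1,
               group_scales = 3,
               control = sampler_control(n_warmup = 300, n_draws = 500,
                                         seed = 3))
  f2 <- hbpois(y = 100, offset = 1000, X = X, coef_groups = 1,
               group_scales = 3,
               control = sampler_control(n_warmup = 300, n_draws = 500,
                                         seed = 4))
  m1 <- median(exp(coef_draws(f1)[, 1, 1]))
  m2 <- median(exp(coef_draws(f2)[, 1, 1]))
  expect_lt(abs(m1 - m2) / m1, 0.12)
})

test_that("sampler output is deterministic for a fixed seed", {
  args <- list(y = matrix(c(10, 50), 1), offset = matrix(c(100, 500), 1),
               X = cbind(intercept = c(1, 1)), coef_groups = 1,
               group_scales = 3,
               control = sampler_control(n_warmup = 100, n_draws = 100,
                                         seed = 99))
  f1 <- do.call(hbpois, args)
  f2 <- do.call(hbpois, args)
  expect_identical(f1$draws, f2$draws)
})

test_that("a too-small tree depth is reported as saturation", {
  set.seed(5)
  U <- 4
  y <- matrix(rpois(U * 10, 30), U, 10)
  off <- matrix(100, U, 10)
  X <- cbind(intercept = rep(1, 10), x = rnorm(10))
  fit <- hbpois(y, off, X, coef_groups = c(1, 2), group_scales = c(3, 1),
                control = sampler_control(n_warmup = 100, n_draws = 100,
                                          max_tree_depth = 1, seed = 2))
  expect_true(fit$convergence$treedepth_saturated)
  expect_false(check_convergence(fit$convergence))
})

test_that("hdi is the shortest window and carries the stated mass", {
  # uniform ranks: any window of ceil(0.95*100) = 95 values has width 94
  h <- hdi(1:100, 0.95)
  expect_equal(h$upper - h$lower, 94)
  # mass property: fraction of draws inside is within 2/n of the target
  set.seed(8)
  for (i in 1:20) {
    x <- rgamma(500, shape = sample(1:5, 1))
    m <- runif(1, 0.5, 0.99)
    h <- hdi(x, m)
    frac <- mean(x >= h$lower & x <= h$upper)
    expect_lte(abs(frac - m), 2 / length(x))
  }
  # symmetric unimodal draws: HDI close to the equal-tailed interval
  set.seed(9)
  x <- rnorm(4000)
  h <- hdi(x, 0.95)
  q <- quantile(x, c(0.025, 0.975))
  width <- h$upper - h$lower
  expect_lt(abs(h$lower - q[[1]]), 0.05 * width)
  expect_lt(abs(h$upper - q[[2]]), 0.05 * width)
  # degenerate draws: zero width
  h0 <- hdi(rep(3.3, 200))
  expect_equal(h0$lower, h0$upper)
  expect_error(hdi(1:200, 1.2), "mass")
})

test_that("rope decisions follow the disjointness rule", {
  rope <- list(lower = 0.49, upper = 0.51)
  ival <- function(lo, hi) list(lower = lo, upper = hi)
  expect_equal(rope_decision(ival(0.52, 0.60), rope), "excludes")
  expect_equal(rope_decision(ival(0.50, 0.60), rope), "overlaps")
  expect_equal(rope_decision(ival(0.40, 0.48), rope), "excludes")
})

test_that("the convergence rule is the conjunction of its three conditions", {
  ok <- convergence_report(1.05, 0, FALSE)
  expect_true(check_convergence(ok))
  expect_false(check_convergence(convergence_report(1.2, 0, FALSE)))
  expect_false(check_convergence(convergence_report(1.0, 1, FALSE)))
  expect_false(check_convergence(convergence_report(1.0, 0, TRUE)))
})

test_that("split R-hat detects chains stuck at different levels", {
  set.seed(11)
  good <- matrix(rnorm(400), 100, 4)
  bad <- good + matrix(rep(c(0, 0, 0, 5), each = 100), 100, 4)
  expect_lt(split_rhat(good), 1.1)
  expect_gt(split_rhat(bad), 1.5)
})
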