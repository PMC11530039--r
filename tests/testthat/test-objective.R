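test_that("penalty profile matches a dense independent evaluation of its branches", {
  w <- loss_weights()
  a <- w$a; b <- w$b; c <- w$c
  # independent piecewise oracle, written directly from the branch formulas
  oracle <- function(nu) {
    vapply(nu, function(v) {
      if (v <= c) cos((pi / 2) * (v - c) / (2 * pi + c - b))
      else if (v <= a) cos((pi / 2) * (v - c) / (a - c))
      else if (v <= b) 0
      else cos((pi / 2) * (v - c - 2 * pi) / (2 * pi + c - b))
    }, 0)
  }
  grid <- seq(-pi + 1e-9, pi, length.out = 20001)
  expect_equal(penalty_profile(grid, w), oracle(grid), tolerance = 1e-12)

  expect_equal(penalty_profile(c, w), 1)
  expect_equal(penalty_profile(a, w), 0)
  expect_equal(penalty_profile(b, w), 0)
  expect_equal(penalty_profile(0, w), 0)
  expect_equal(penalty_profile(-pi / 2, w), 0.8614522108, tolerance = 1e-9)

  # identically zero on the permitted band, maximum 1 at c
  band <- seq(a + 1e-12, b, length.out = 501)
  expect_true(all(penalty_profile(band, w) == 0))
  expect_true(all(penalty_profile(grid, w) <= 1))
  expect_equal(max(penalty_profile(grid, w)), 1, tolerance = 1e-8)

  # continuity at the breakpoints and across the +/- pi wrap
  eps <- 1e-9
  for (x0 in c(c, a, b)) {
    expect_lt(abs(penalty_profile(x0 + eps, w) - penalty_profile(x0, w)),
              1e-7)
  }
  expect_lt(abs(penalty_profile(-pi + eps, w) - penalty_profile(pi, w)), 1e-7)

  expect_error(penalty_profile(3.5, w), "range|\\(-pi, pi\\]")
})

test_that("phase progression recovers rotation angles and their sign", {
  expect_equal(phase_progression(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(phase_progression(c(0, 1), c(1, 0)), -pi / 2)
  expect_equal(phase_progression(c(0, 1), c(0, 1)), 0)

  set.seed(41)
  for (i in 1:200) {
    th <- runif(1, -pi, pi)
    u <- c(cos(runif(1, -pi, pi)), 0)
    u[2] <- sqrt(1 - u[1]^2) * sign(runif(1, -1, 1))
    expect_equal(phase_progression(u, rotate2(u, th)), th, tolerance = 1e-9)
  }
  expect_error(phase_progression(c(1, 1), c(0, 1)), "unit")
})

test_that("loss components obey their closed-form laws on constructed outputs", {
  w <- loss_weights()
  terms <- function(Vc, Vp = Vc, Vn = Vc, guard = FALSE) {
    gaitphase:::.loss_terms(Vp, Vc, Vn, w, guard = guard)
  }
  # balanced antipodal outputs: centroid at the origin, D = 0
  ang <- c(0, pi / 2, pi, -pi / 2)
  Vbal <- 3 * cbind(cos(ang), sin(ang))
  expect_equal(terms(Vbal)$d, 0, tolerance = 1e-15)
  # collapsed outputs: D = alpha
  Vcol <- cbind(rep(2, 5), rep(0, 5))
  expect_equal(terms(Vcol)$d, 0.45)
  # single pair at nu = c contributes a full phase-progression penalty
  u <- c(cos(0.3), sin(0.3))
  pair <- terms(Vc = matrix(rotate2(u, w$c), 1), Vp = matrix(u, 1))
  expect_equal(pair$pp, 1, tolerance = 1e-9)
  # S at the origin equals gamma / (sigma sqrt(2 pi)) (guard disabled)
  V0 <- matrix(0, 3, 2)
  expect_equal(terms(Vc = V0, Vp = Vbal[1:3, ])$s, 0.2194182542,
               tolerance = 1e-9)
  # S and M strictly decrease in |V|
  r <- seq(0, 4, by = 0.1)
  svals <- vapply(r, function(ri)
    terms(Vc = matrix(c(ri, 0), 1))$s, 0)
  mvals <- vapply(r, function(ri)
    terms(Vc = matrix(c(1, 0), 1), Vn = matrix(c(0, ri), 1))$m, 0)
  expect_true(all(diff(svals) < 0))
  expect_true(all(diff(mvals) < 0))
  # D never exceeds alpha, and the total is the weighted sum
  lt <- terms(Vc = Vbal + 0.3, Vp = Vbal, Vn = Vbal - 0.2)
  expect_lte(lt$d, w$alpha + 1e-12)
  expect_equal(lt$total, w$pp_weight * lt$pp + lt$d + lt$s + lt$m)
})

test_that("singularity guard reports the offending pair", {
  w <- loss_weights()
  V <- rbind(c(1, 0), c(0, 0), c(0, 1))
  expect_error(gaitphase:::.loss_terms(V, V, V, w), "pair 2")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(51)
  p <- init_params(13L)
  n <- 25L
  prev <- matrix(rnorm(n * 28), n, 28)
  curr <- matrix(rnorm(n * 28), n, 28)
  noisy <- curr + matrix(rnorm(n * 28, 0, 0.1), n, 28)
  w <- loss_weights()
  lg <- gaitphase:::.loss_and_grad(p, prev, curr, noisy, w)
  theta <- gaitphase:::.flatten_params(p)
  g <- gaitphase:::.flatten_params(lg$grads)

  total_at <- function(th) {
    q <- gaitphase:::.unflatten_params(th, p)
    gaitphase:::.loss_terms(gaitphase:::.forward(q, prev),
                            gaitphase:::.forward(q, curr),
                            gaitphase:::.forward(q, noisy), w)$total
  }
  h <- 1e-6
  idx <- sample(length(theta), 20L)
  for (k in idx) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    fd <- (total_at(tp) - total_at(tm)) / (2 * h)
    expect_lt(abs(fd - g[k]) / max(abs(fd), abs(g[k]), 1e-8), 1e-4)
  }
})

test_that("loss breakdown is reproducible and rejects empty batches", {
  w <- quiet_walk(duration_s = 2, noise_sd = 0.3, seed = 14L)
  wf <- walk_features(w)
  pairs <- build_window_pairs(wf$feat)
  p <- init_params(4L)
  l1 <- loss_breakdown(p, pairs, noise_seed = 99L)
  l2 <- loss_breakdown(p, pairs, noise_seed = 99L)
  expect_identical(unclass(l1), unclass(l2))
  expect_equal(l1$total, l1$pp + l1$d + l1$s + l1$m)
  expect_equal(l1$n_pairs, nrow(pairs$curr))

  empty <- structure(list(prev = matrix(numeric(0), 0, 28),
                          curr = matrix(numeric(0), 0, 28)),
                     class = "window_pairs")
  expect_error(loss_breakdown(p, empty), "empty")
})

test_that("training descends the loss and is reproducible from the seed", {
  w <- quiet_walk(duration_s = 20, cadence = 1, noise_sd = 0.5, seed = 1L)
  wf <- walk_features(w)
  pairs <- build_window_pairs(wf$feat)
  cfg <- train_config(iterations = 500L, batch_size = 512L, seed = 1L)
  fit <- train_phase_model(pairs, cfg)
  expect_equal(nrow(fit$history), 500L)
  expect_named(fit$history, c("iteration", "pp", "d", "s", "m", "total"))
  expect_lt(tail(fit$history$total, 1), fit$history$total[1])

  fit2 <- train_phase_model(pairs, cfg)
  expect_identical(gaitphase:::.flatten_params(fit2$params),
                   gaitphase:::.flatten_params(fit$params))
})
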