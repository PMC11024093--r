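test_that("model evaluation obeys its closed-form limits", {
  set.seed(11)
  tt <- seq(0, 3000, by = 30)
  for (i in 1:50) {
    p <- random_params()
    f <- model_eval(tt, p)
    expect_identical(f[1], 0)  # onset exactly at baseline
    # equal-rate limit collapses to a single saturating exponential
    p0 <- transient_params(p$tau_decay, 0, p$b, p$c)
    expect_equal(model_eval(tt, p0), p$c * (1 - exp(-p$tau_decay * tt)))
    # long-time limit is the steady state c
    t_inf <- 20 / p$tau_decay
    expect_lt(abs(model_eval(t_inf, p) - p$c), 1e-6 * max(1, p$c))
  }
  expect_error(model_eval(-1, random_params()), "non-negative")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(transient_params(-0.01, 0, 1, 1), "tau_decay")
  expect_error(transient_params(0.01, -1, 1, 1), "tau_delta")
  expect_error(transient_params(0.01, 0.01, -1, 1), "'b'")
  p <- transient_params(0.01, 0.005, 3, 2)
  expect_equal(param_a(p), 5)
  expect_equal(param_tau_rise(p), 0.015)
  expect_gte(param_a(p), p$b)
  expect_gte(param_tau_rise(p), p$tau_decay)
})

test_that("peak time maximises the model on a dense grid", {
  set.seed(21)
  for (i in 1:30) {
    p <- random_params()
    ts <- peak_time(p)
    grid <- seq(0, max(4 * ts, 60 / p$tau_decay), length.out = 4000)
    expect_gte(model_eval(ts, p), max(model_eval(grid, p)) - 1e-10)
  }
  # no steady-state component: the closed form simplifies
  p <- transient_params(1 / 200, 0.02, 5, 0)
  expect_equal(peak_time(p),
               log(param_tau_rise(p) / p$tau_decay) / p$tau_delta)
  # raising the steady state delays the peak
  tstars <- sapply(c(0.5, 2, 8, 32), function(cc)
    peak_time(transient_params(1 / 200, 0.02, 5, cc)))
  expect_true(all(diff(tstars) > 0))
  # monotone cases have no interior peak
  expect_error(peak_time(transient_params(1 / 200, 0, 5, 1)),
               class = "calshape_no_peak")
  expect_error(peak_time(transient_params(1 / 200, 0.02, 0, 1)),
               class = "calshape_no_peak")
})

test_that("fit eligibility criteria flag flat, late-peaked and real responders", {
  flat <- rep(5, 60)
  cr <- check_fit_criteria(flat)
  expect_false(cr$responsive)
  expect_false(cr$eligible)

  rising <- seq(0, 10, length.out = 60)  # maximum at the final frame
  cr <- check_fit_criteria(rising)
  expect_false(cr$peak_in_first_half)
  expect_false(cr$eligible)

  p <- transient_params(1 / 150, 0.03, 80, 20)
  y <- simulate_transient(p, 60, 30, 9, noise_sd = 0, f0 = 100)
  cr <- check_fit_criteria(y)
  expect_true(cr$median_nonnegative)
  expect_true(cr$responsive)
  expect_true(cr$peak_in_first_half)
  expect_true(cr$eligible)
})

test_that("initialisation grid has the documented size, ranges and order", {
  yprime <- c(0, 2, 5, 4, 3, 2.5)
  g <- grid_candidates(yprime)
  expect_equal(nrow(g), 300)
  expect_equal(length(unique(g$tau_decay)), 10)
  expect_equal(length(unique(g$tau_delta)), 6)
  expect_equal(length(unique(g$b)), 5)
  expect_equal(min(g$tau_decay), 1 / 1500)
  expect_equal(max(g$tau_decay), 1 / 15)
  expect_equal(range(g$tau_delta), c(1e-6, 1e-1))
  expect_equal(range(g$b), c(0.1, 1000))
  expect_true(all(g$c == median(yprime)))
  # lexicographic emission order in (tau_decay, tau_delta, b)
  key <- order(g$tau_decay, g$tau_delta, g$b)
  expect_identical(key, seq_len(300))
  expect_true(all(g$tau_decay >= 0 & g$tau_delta >= 0 & g$b >= 0))
  expect_error(grid_candidates(c(-3, -2, -1, 0)), "negative")
})

test_that("bounded multi-start fit recovers known kinetics", {
  tt <- (0:51) * 30
  truths <- list(transient_params(1 / 120, 0.03, 150, 40),
                 transient_params(1 / 600, 0.015, 60, 15),
                 transient_params(1 / 60, 0.05, 300, 100))
  for (p in truths) {
    fit <- fit_transient(model_eval(tt, p), tt)
    expect_true(fit$converged)
    expect_equal(fit$n_starts_evaluated, 300)
    expect_lt(abs(1 / fit$params$tau_decay - 1 / p$tau_decay) *
                p$tau_decay, 0.01)
    expect_lt(abs(fit$params$c - p$c) / p$c, 0.01)
    # bounds respected
    expect_lte(fit$params$c, max(model_eval(tt, p)))
  }
})

test_that("near-instant rise to a plateau recovers the plateau level", {
  tt <- (0:51) * 30
  p <- transient_params(1e-9, 5, 0.001, 2)  # step to c = 2
  fit <- fit_transient(model_eval(tt, p), tt)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$c - 2) / 2, 0.01)
})

test_that("fitting is deterministic and never beaten by any single start", {
  set.seed(31)
  tt <- (0:51) * 30
  p <- random_params()
  y <- model_eval(tt, p) + rnorm(52, 0, 0.05 * max(model_eval(tt, p)))
  f1 <- fit_transient(y, tt)
  f2 <- fit_transient(y, tt)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$r2_error, f2$r2_error)
  # the reported minimum is no worse than the raw cost at any grid start
  g <- grid_candidates(y)
  ssr_at <- function(row) {
    q <- transient_params(row$tau_decay, row$tau_delta, row$b,
                          min(row$c, max(y)))
    sum((y - model_eval(tt, q))^2)
  }
  for (i in sample(nrow(g), 20)) {
    expect_lte(f1$r2_error, ssr_at(g[i, ]))
  }
})

test_that("cohort fitting skips ineligible cells and labels responders", {
  spec <- cohort_spec(n_cells = 5, noise_sd = 1, seed = 42,
                      nonresponder_fraction = 0.2)
  ch <- simulate_cohort(spec)
  fits <- fit_cohort(drop_first_frame(ch$traces))
  expect_equal(nrow(fits), nrow(ch$truth))
  nonresp <- !ch$truth$responder
  expect_true(all(!fits$eligible[nonresp]))
  expect_true(all(is.na(fits$inv_tau_decay[!fits$eligible])))
  fitted <- fits$eligible & fits$converged
  expect_true(any(fitted))
  rel <- abs(fits$inv_tau_decay[fitted] - ch$truth$inv_tau_decay[fitted]) /
    ch$truth$inv_tau_decay[fitted]
  expect_lt(median(rel), 0.15)
})
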