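test_that("tolerance windows are centred, closed and must be disjoint", {
  expect_equal(tolerance_windows(100, 1), cbind(lo = 100, hi = 100))
  expect_equal(tolerance_windows(100, 3), cbind(lo = 99, hi = 101))
  expect_error(tolerance_windows(c(50, 53), 5), "overlap")
  expect_error(tolerance_windows(100, 2), "odd")
  expect_error(learn_config(epsilon = 4), "odd")
})

test_that("first-error detection reports each error type at the right time", {
  expect_null(find_first_error(c(30, 90), c(30, 90), 1))
  expect_null(find_first_error(c(29, 91), c(30, 90), 3))
  e <- find_first_error(numeric(0), c(100, 200), 1)
  expect_equal(e$kind, "c"); expect_equal(e$t_err, 100)
  e <- find_first_error(c(100, 150), c(100, 200), 3)
  expect_equal(e$kind, "a"); expect_equal(e$t_err, 150)
  e <- find_first_error(c(99, 101), 100, 3)
  expect_equal(e$kind, "b"); expect_equal(e$t_err, 101)
  # a stray spike at the closing edge of an unfilled window: missed window wins
  e <- find_first_error(c(101), c(98), 3)
  expect_equal(e$kind, "c"); expect_equal(e$t_err, 98)
})

test_that("first-error detection agrees with the brute-force event walk", {
  set.seed(42)
  for (rep in 1:300) {
    eps <- sample(c(1, 3, 5), 1)
    desired <- sort(sample(seq(5, 120, by = eps + 2),
                           sample(0:3, 1)))
    actual <- sort(sample(0:125, sample(0:6, 1)))
    got <- find_first_error(actual, desired, eps)
    ref <- ref_first_error(actual, desired, eps)
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_equal(got$kind, ref$kind,
                   label = paste("kind for", paste(actual, collapse = ","),
                                 "vs", paste(desired, collapse = ","), "eps", eps))
      expect_equal(got$t_err, ref$t_err)
    }
  }
})

test_that("voltage time derivative matches closed form and finite differences", {
  p <- neuron_params()
  empty <- spike_pattern(list(numeric(0)), duration = 100)
  expect_equal(voltage_time_derivative(50, empty, 1, numeric(0), p), 0)
  # single input spike closed form
  pat1 <- spike_pattern(list(20), duration = 100)
  w <- 0.8
  t_spike <- 27
  expect_equal(
    voltage_time_derivative(t_spike, pat1, w, numeric(0), p),
    p$v_norm * w * (exp(-7 / p$tau_s) / p$tau_s - exp(-7 / p$tau_m) / p$tau_m),
    tolerance = 1e-12)
  # finite-difference agreement in smooth regions, with prior resets
  for (seed in 1:10) {
    inst <- random_instance(seed)
    prior <- inst$desired[1:2]
    t_spike <- inst$desired[3] + 0.5  # off-grid: no kink at the query time
    ana <- voltage_time_derivative(t_spike, inst$pattern, inst$weights,
                                   prior, inst$params)
    num <- fd(function(t) ref_potential(t, inst$pattern, inst$weights,
                                        prior, inst$params), t_spike)
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("weight increment reduces to the PSP column when no earlier target exists", {
  p <- neuron_params()
  inst <- random_instance(1)
  cfg <- learn_config(epsilon = 1, s_r = 2, lambda1 = 0.01, lambda2 = 0.01)
  dw <- weight_increment(inst$pattern, inst$weights, numeric(0),
                         inst$desired[1], cfg, p)
  direct <- vapply(inst$pattern$trains, function(s) {
    sum(psp_kernel(inst$desired[1] - s[s < inst$desired[1]], p))
  }, 0.0)
  expect_equal(dw, 0.01 * direct, tolerance = 1e-9)
})

test_that("with the scaling rate off, increment and decrement are mirror images", {
  p <- neuron_params()
  inst <- random_instance(2)
  cfg <- learn_config(epsilon = 1, s_r = 0, lambda1 = 0.004, lambda2 = 0.004)
  t_err <- inst$desired[3]
  up <- weight_increment(inst$pattern, inst$weights,
                         inst$desired[inst$desired < t_err], t_err, cfg, p)
  down <- weight_decrement(inst$pattern, t_err, cfg, p)
  expect_equal(up, -down, tolerance = 1e-12)
})

test_that("analytic weight updates match finite-difference oracles", {
  expect_gte(check_gradient_oracles(25), 25)
})

test_that("small weight updates move the potential at the error time the right way", {
  p <- neuron_params()
  inst <- random_instance(3)
  cfg <- learn_config(epsilon = 1, s_r = 1, lambda1 = 1e-4, lambda2 = 1e-4)
  t_err <- inst$desired[3]
  db <- inst$desired[inst$desired < t_err]
  v_at <- function(w) ref_potential(t_err, inst$pattern, w, db, inst$params)
  v0 <- v_at(inst$weights)
  up <- weight_increment(inst$pattern, inst$weights, db, t_err, cfg, p)
  expect_gt(v_at(inst$weights + up), v0)
  down <- weight_decrement(inst$pattern, t_err, cfg, p)
  expect_lt(v_at(inst$weights + down), v0)
})

test_that("training applies one update per epoch and reports convergence honestly", {
  p <- neuron_params()
  pat <- poisson_pattern(50, 10, 100, seed = 11)
  cfg <- learn_config(epsilon = 3, max_epochs = 2000, seed = 123,
                      lambda1 = 0.01, lambda2 = 0.01)
  rec <- fe_train(pat, 50, cfg, p)
  expect_true(rec$converged)
  expect_equal(rec$epochs_to_converge, length(rec$c_history) - 1L)
  expect_equal(nrow(rec$error_log), length(rec$c_history))
  # every epoch before convergence logged exactly one error
  expect_true(all(rec$error_log$error_type[-nrow(rec$error_log)] %in%
                    c("a", "b", "c")))
  expect_equal(rec$error_log$error_type[nrow(rec$error_log)], "")
  expect_equal(rec$best_c, max(rec$c_history))
  # converged weights reproduce a train matching every window
  tr <- simulate_lif(pat, rec$weights, p)
  expect_null(find_first_error(tr$output_spikes, 50, 3))
  # restarting from the converged weights needs zero further updates
  rec2 <- fe_train(pat, 50, cfg, p, weights = rec$weights)
  expect_true(rec2$converged)
  expect_equal(rec2$epochs_to_converge, 0L)
})

test_that("the rule reliably learns a one-spike target on a small task", {
  p <- neuron_params()
  ok <- 0
  for (s in 1:20) {
    pat <- poisson_pattern(50, 10, 100, seed = s)
    cfg <- learn_config(epsilon = 3, max_epochs = 2000, seed = 1000 + s)
    rec <- fe_train(pat, 50, cfg, p)
    ok <- ok + rec$converged
  }
  expect_gte(ok, 18)
})

test_that("exact-window convergence forces a perfect correlation score", {
  p <- neuron_params()
  for (s in 1:3) {
    pat <- poisson_pattern(80, 15, 200, seed = 100 + s)
    desired <- poisson_train(40, 200, seed = 200 + s, t_min = 1, min_gap = 1)
    cfg <- learn_config(epsilon = 1, max_epochs = 8000, seed = 300 + s)
    rec <- fe_train(pat, desired, cfg, p)
    if (rec$converged) {
      expect_identical(rec$c_history[length(rec$c_history)], 1)
      expect_equal(rec$best_c, 1)
    }
  }
})
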