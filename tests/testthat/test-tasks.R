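test_that("template matching picks the most similar class", {
  tpl <- list(seq(5, 170, 15), seq(15, 180, 15), seq(25, 190, 15))
  expect_equal(classify_by_template(tpl[[2]], tpl, duration = 200), 2)
  expect_equal(classify_by_template(tpl[[3]], tpl, duration = 200), 3)
  # empty output ties at zero and falls back to the first class
  expect_equal(classify_by_template(numeric(0), tpl, duration = 200), 1)
  # a slightly jittered copy still matches its own template
  expect_equal(classify_by_template(seq(5, 170, 15) + 1, tpl, duration = 200), 1)
})

test_that("dynamic target determination follows the readout rules", {
  p <- neuron_params()
  cfg <- dynamic_decode_config(theta_e = 0.6)
  mk_trace <- function(values, spikes) {
    structure(list(values = values,
                   times = seq(0, length.out = length(values), by = 1),
                   output_spikes = spikes, params = p,
                   duration = length(values) - 1),
              class = "voltage_trace")
  }
  # non-target, silent: nothing to learn
  r <- dynamic_targets(FALSE, mk_trace(rep(0.2, 200), numeric(0)), cfg)
  expect_length(r$desired, 0); expect_null(r$update)
  # non-target with output: decrement at the first actual spike
  r <- dynamic_targets(FALSE, mk_trace(rep(0.2, 200), c(80, 120)), cfg)
  expect_equal(r$update, "decrement"); expect_equal(r$t_err, 80)
  # target, silent, subthreshold peak at 120 ms
  v <- rep(0.1, 200); v[121] <- 0.8
  r <- dynamic_targets(TRUE, mk_trace(v, numeric(0)), cfg)
  expect_equal(r$desired, 120); expect_equal(r$t_err, 120)
  expect_equal(r$update, "increment")
  # target with spikes and V_max above the encoding threshold
  v <- rep(0.1, 200); v[81] <- 1.2; v[151] <- 0.7
  r <- dynamic_targets(TRUE, mk_trace(v, 80), cfg)
  expect_equal(r$desired, c(80, 150)); expect_equal(r$t_err, 150)
  expect_equal(r$update, "increment")
  # target with spikes and V_max at or below the threshold: keep the output
  v <- rep(0.1, 200); v[81] <- 1.2; v[151] <- 0.6
  r <- dynamic_targets(TRUE, mk_trace(v, 80), cfg)
  expect_equal(r$desired, 80); expect_null(r$update)
})

test_that("dynamic targets never schedule two opposing updates at once", {
  p <- neuron_params()
  cfg <- dynamic_decode_config(theta_e = 0.5)
  set.seed(31)
  for (rep in 1:40) {
    pat <- poisson_pattern(30, 30, 100, seed = rep)
    w <- rnorm(30, 0.05, 0.15)
    tr <- simulate_lif(pat, w, p)
    for (tgt in c(TRUE, FALSE)) {
      r <- dynamic_targets(tgt, tr, cfg)
      expect_true(is.null(r$update) ||
                    r$update %in% c("increment", "decrement"))
      if (!is.null(r$update)) expect_length(r$t_err, 1)
      if (!tgt) expect_length(r$desired, 0)
    }
  }
})

test_that("population readout counts activated neurons per index", {
  # hand-evaluated example: G = 2 groups, M = 3 neurons each
  counts <- rbind(c(3, 0, 2), c(1, 1, 1))
  r <- population_predict(counts)
  expect_equal(r$activated, c(2L, 1L))
  expect_equal(r$predicted_group, 1)
  # dominant group wins at every index
  r <- population_predict(rbind(c(1, 1, 1), c(4, 5, 6), c(0, 2, 1)))
  expect_equal(r$predicted_group, 2)
  # all silent: every index ties, fallback to the first group
  r <- population_predict(matrix(0, 3, 4))
  expect_equal(r$activated, c(0L, 0L, 0L))
  expect_equal(r$predicted_group, 1)
  # permutation equivariance up to the tie rule
  set.seed(8)
  for (rep in 1:20) {
    counts <- matrix(sample(0:5, 12, replace = TRUE), 3, 4)
    perm <- sample(3)
    a <- population_predict(counts)
    b <- population_predict(counts[perm, , drop = FALSE])
    expect_equal(b$activated, a$activated[perm])
    if (sum(a$activated == max(a$activated)) == 1) {
      expect_equal(b$predicted_group, which(perm == a$predicted_group))
    }
  }
})

test_that("noiseless classification data is learned to perfect training accuracy", {
  ds <- make_classification_dataset(n_afferents = 120, base_rate = 5,
                                    n_train = 4, n_test = 4, jitter_sd = 0,
                                    seed = 5)
  cfg <- learn_config(epsilon = 3, seed = 17)
  model <- fit_pattern_classifier(ds, cfg, epochs = 150)
  expect_equal(classifier_accuracy(model, ds$train), 1)
  expect_equal(classifier_accuracy(model, ds$test), 1)
})

test_that("a dynamically decoded population learns a small two-class task", {
  ds <- make_classification_dataset(n_classes = 2, n_afferents = 100,
                                    base_rate = 10, duration = 100,
                                    n_train = 8, n_test = 8, jitter_sd = 1,
                                    templates = list(c(30, 60), c(45, 80)),
                                    seed = 7)
  dp <- fit_dynamic_population(
    ds, learn_config(seed = 7),
    dynamic_decode_config(theta_e = 0.6, group_count = 2,
                          neurons_per_group = 3),
    epochs = 15)
  expect_gte(mean(predict(dp, ds$train$patterns) == ds$train$labels), 0.9)
  expect_gte(mean(predict(dp, ds$test$patterns) == ds$test$labels), 0.75)
})

test_that("the experiment runner rejects unknown protocols and writes outputs", {
  expect_error(run_experiment("nope"), "unknown experiment")
  out <- tempfile()
  res <- run_experiment("classification", seeds = 1,
                        n_afferents = 60, n_train = 3, n_test = 3,
                        epochs = 30, out_dir = out)
  expect_true(file.exists(file.path(out, "classification.csv")))
  expect_true(file.exists(file.path(out, "classification_summary.json")))
  expect_true(all(c("train_accuracy", "test_accuracy") %in% names(res)))
})
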