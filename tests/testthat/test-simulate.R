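test_that("network specifications are validated", {
  expect_error(
    network_spec(c(A = 0.2, B = 0.3, C = 0.4),
                 list(c("A", "B"))),
    "no study"
  )
  expect_error(
    network_spec(c(A = 0.2, B = 0.3, C = 0.4, D = 0.5),
                 list(c("A", "B"), c("C", "D"))),
    "disconnected"
  )
  expect_error(
    network_spec(c(A = 0.2), list(c("A", "B"))),
    "without a risk"
  )
  expect_error(
    network_spec(c(A = 0.2, B = 0.3), list(c("A", "B")), arm_size = 1),
    ">= 2"
  )
})

test_that("the default synthetic network has the documented scale", {
  spec <- brd_network_spec()
  expect_length(spec$risks, 13)
  expect_length(spec$studies, 98)
  expect_equal(sum(lengths(spec$studies)), 204)
  expect_equal(sum(lengths(spec$studies) == 3), 8)
  expect_equal(unname(spec$risks["NAC"]), 0.68)
  # the planned comparison has no direct edge
  expect_false(any(vapply(spec$studies, function(s)
    all(c("CEFTP", "TILD") %in% s), TRUE)))
  net <- generate_network(spec, seed = 1)
  expect_equal(nrow(net$arms), 204)
})

test_that("network generation is deterministic and unbiased at scale", {
  spec <- small_spec()
  a <- generate_network(spec, seed = 11)
  b <- generate_network(spec, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_network(spec, seed = 12)))

  big <- network_spec(c(A = 0.5, B = 0.5, C = 0.5),
                      list(c("A", "C"), c("B", "C")), arm_size = 10000)
  net <- generate_network(big, seed = 3)
  expect_true(all(abs(net$contrasts$TE) <= 4 * net$contrasts$seTE))
})

test_that("resampling preserves the layout and targets the supplied risks", {
  spec <- small_spec()
  arms <- generate_network(spec, seed = 2)$arms
  res <- resample_network(arms, spec$risks, seed = 5)
  expect_equal(res$n, arms$n)
  expect_equal(res$studlab, arms$studlab)
  expect_identical(res, resample_network(arms, spec$risks, seed = 5))
  expect_error(resample_network(arms, c(A = 0.2), seed = 1),
               "no risk supplied")

  # mean TE over many resamples of one study approaches the true contrast
  one <- tibble::tibble(studlab = "s1", treat = c("A", "B"),
                        r = c(0L, 0L), n = c(200L, 200L))
  risks <- c(A = 0.25, B = 0.45)
  set.seed(99)
  te <- replicate(1000, {
    arms_to_contrasts(resample_network(one, risks))$TE
  })
  truth <- lor_from_risks(risks[["B"]], risks[["A"]]) # TE is A relative to B
  expect_lt(abs(mean(te) - truth), 4 * sd(te) / sqrt(1000))
})

test_that("a simulated trial matches its design variance", {
  tr <- simulate_new_trial(0.2, 0.3, 100, 100, seed = 7)
  expect_identical(tr, simulate_new_trial(0.2, 0.3, 100, 100, seed = 7))
  set.seed(123)
  te <- replicate(4000, simulate_new_trial(0.2, 0.3, 150, 130)$TE)
  expect_equal(sd(te), sqrt(trial_variance(0.2, 0.3, 150, 130)),
               tolerance = 0.05)
})

test_that("the simulation engine equals a full network refit", {
  spec <- small_spec()
  net <- generate_network(spec, seed = 21)
  eng <- nmadesign:::make_network_engine(net$arms, "A", "B")
  set.seed(31)
  r <- rbinom(nrow(net$arms), net$arms$n, spec$risks[net$arms$treat])
  fit <- nmadesign:::engine_fit(eng, r)
  arms2 <- net$arms
  arms2$r <- r
  contr <- arms_to_contrasts(arms2)
  full <- fit_nma(contr)
  expect_equal(fit$sigma_pair, full$se_matrix["A", "B"], tolerance = 1e-10)

  # rank-one update equals refitting the enlarged network
  set.seed(32)
  res <- nmadesign:::analyse_replicate(eng, fit, 0.2, 0.3, 120, 100,
                                       qnorm(0.975))
  set.seed(32)
  trial <- simulate_new_trial(0.2, 0.3, 120, 100, treat1 = "A",
                              treat2 = "B")
  upd <- update_network(contr, trial[, 1:5])
  expect_equal(res$se_w, upd$se_matrix["A", "B"], tolerance = 1e-10)
})

test_that("fixed-total validation is deterministic and network-dominant", {
  spec <- small_spec()
  net <- generate_network(spec, seed = 8)
  out <- simulate_design_fixed_total(net$arms, spec$risks, "A", "B",
                                     lor = 0.5, n_total = 400,
                                     n_reps = 200, seed = 14)
  expect_identical(out, simulate_design_fixed_total(
    net$arms, spec$risks, "A", "B", lor = 0.5, n_total = 400,
    n_reps = 200, seed = 14))
  expect_named(out, c("allocation", "method", "n1", "n2", "sim_power",
                      "formula_power", "sim_se", "formula_se",
                      "zero_cell_rate", "n_reps"))
  expect_equal(nrow(out), 4)
  wide <- tidyr::pivot_wider(out[, c("allocation", "method", "sim_power")],
                             names_from = "method",
                             values_from = "sim_power")
  expect_true(all(wide$with > wide$without))

  # a direct comparison in the existing network is rejected
  direct <- network_spec(c(A = 0.2, B = 0.3),
                         list(c("A", "B")), arm_size = 50)
  expect_error(
    simulate_design_fixed_total(generate_network(direct, 1)$arms,
                                direct$risks, "A", "B", 0.5, 100),
    "direct comparison"
  )
})

test_that("type-I error is controlled at a null effect", {
  spec <- small_spec()
  net <- generate_network(spec, seed = 4)
  out <- simulate_design_fixed_total(net$arms, spec$risks, "A", "B",
                                     lor = 0, n_total = 400,
                                     n_reps = 300, seed = 5)
  expect_true(all(out$sim_power <= 0.12))
  expect_equal(out$formula_power[out$method == "without"], c(0.05, 0.05))
})

test_that("target-power validation reaches the goal with the network", {
  spec <- small_spec()
  net <- generate_network(spec, seed = 6)
  out <- simulate_design_target_power(net$arms, spec$risks, "A", "B",
                                      lor = 0.5, power.level = 0.8,
                                      n_reps = 300, seed = 16)
  expect_identical(out, simulate_design_target_power(
    net$arms, spec$risks, "A", "B", lor = 0.5, power.level = 0.8,
    n_reps = 300, seed = 16))
  expect_equal(nrow(out), 4)
  expect_true(all(out$mean_total > 0))
  with_rows <- out[out$method == "with", ]
  expect_true(all(abs(with_rows$sim_power - 0.8) <
                    3 * sqrt(0.8 * 0.2 / 300) + 0.02))
  expect_true(all(with_rows$sim_power >
                    out$sim_power[out$method == "without"]))
  expect_s3_class(plot_simulation_power(out), "ggplot")
})

test_that("scenario configs dispatch to the right protocol", {
  config <- list(
    treatments = list(A = 0.2, B = 0.3, C = 0.5),
    studies = list(c("A", "C"), c("B", "C")),
    arm_size = 150,
    treat1 = "A", treat2 = "B", lor = 0.5,
    n_total = 300, n_reps = 50, seed = 2
  )
  out <- simulate_scenario(config)
  expect_equal(nrow(out), 4)
  expect_true("n1" %in% names(out))

  config$n_total <- NULL
  config$power_level <- 0.8
  out2 <- simulate_scenario(config)
  expect_true("mean_total" %in% names(out2))

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(config, path, auto_unbox = TRUE)
  expect_equal(simulate_scenario(path), out2)

  config$treat1 <- NULL
  expect_error(simulate_scenario(config), "missing field")
})
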