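test_that("design matrix follows the two-case sign rule", {
  one <- tibble::tibble(studlab = "s1", treat1 = "A", treat2 = "B",
                        TE = 1.5, seTE = 0.4)
  dm <- nma_design_matrix(one, baseline = "A")
  expect_equal(unname(dm$X), matrix(-1, 1, 1))
  expect_equal(dm$y, 1.5)

  two <- tibble::tibble(
    studlab = c("s1", "s2"), treat1 = c("A", "B"), treat2 = c("C", "C"),
    TE = c(0.1, 0.2), seTE = c(0.3, 0.3)
  )
  dm <- nma_design_matrix(two, baseline = "C")
  expect_equal(colnames(dm$X), c("A", "B"))
  expect_equal(unname(dm$X), rbind(c(1, 0), c(0, 1)))

  chain3 <- tibble::tibble(
    studlab = c("s1", "s2", "s3"),
    treat1 = c("A", "B", "A"), treat2 = c("B", "C", "C"),
    TE = c(0.1, 0.2, 0.3), seTE = c(0.3, 0.3, 0.3)
  )
  dm <- nma_design_matrix(chain3, baseline = "A")
  expect_equal(colnames(dm$X), c("B", "C"))
  expect_equal(unname(dm$X), rbind(c(-1, 0), c(1, -1), c(0, -1)))
  expect_equal(dm$weights, rep(1 / 0.09, 3))
})

test_that("closed-form identities: single edge, pooling, chain, star", {
  one <- tibble::tibble(studlab = "s1", treat1 = "A", treat2 = "B",
                        TE = 1.5, seTE = 0.4)
  fit <- fit_nma(one)
  expect_equal(fit$te_matrix["A", "B"], 1.5)
  expect_equal(fit$se_matrix["A", "B"], 0.4)

  pooled <- fit_nma(tibble::tibble(
    studlab = c("s1", "s2"), treat1 = "A", treat2 = "B",
    TE = c(1, 2), seTE = 0.2
  ))
  expect_equal(pooled$te_matrix["A", "B"], 1.5)
  expect_equal(pooled$se_matrix["A", "B"], 0.2 / sqrt(2))

  expect_equal(indirect_se(chain_data(), "A", "B"), 0.5)

  k <- 7; s <- 0.35
  star <- tibble::tibble(
    studlab = sprintf("s%d", 1:k), treat1 = "A", treat2 = "B",
    TE = rnorm(k), seTE = s
  )
  expect_equal(indirect_se(star, "A", "B"), s / sqrt(k))
})

test_that("fit equals a dense normal-equations evaluation on random networks", {
  set.seed(77)
  for (i in 1:10) {
    dat <- random_network_data(sample(3:5, 1), n_extra = sample(1:3, 1))
    fit <- fit_nma(dat)
    # independent dense route: explicit X and S, direct inversion
    treats <- sort(unique(c(dat$treat1, dat$treat2)))
    basic <- treats[-1]
    X <- matrix(0, nrow(dat), length(basic))
    colnames(X) <- basic
    for (j in seq_len(nrow(dat))) {
      if (dat$treat1[j] != treats[1]) X[j, dat$treat1[j]] <- 1
      if (dat$treat2[j] != treats[1]) {
        X[j, dat$treat2[j]] <- X[j, dat$treat2[j]] - 1
      }
    }
    Sinv <- solve(diag(dat$seTE^2))
    M <- solve(t(X) %*% Sinv %*% X)
    mu <- M %*% t(X) %*% Sinv %*% dat$TE
    expect_equal(unname(fit$basic_estimates), unname(drop(mu)),
                 tolerance = 1e-10)
    expect_equal(unname(fit$basic_cov), unname(M), tolerance = 1e-10)
  }
})

test_that("pairwise matrices are baseline invariant and internally consistent", {
  set.seed(5)
  dat <- random_network_data(5, n_extra = 3)
  ref <- fit_nma(dat)
  for (b in ref$treatments) {
    alt <- fit_nma(dat, baseline = b)
    expect_equal(alt$te_matrix, ref$te_matrix, tolerance = 1e-10)
    expect_equal(alt$se_matrix, ref$se_matrix, tolerance = 1e-10)
  }
  te <- ref$te_matrix
  expect_equal(te, -t(te), tolerance = 1e-12)
  expect_equal(ref$se_matrix, t(ref$se_matrix), tolerance = 1e-12)
  expect_equal(unname(diag(te)), rep(0, 5))
  tr <- ref$treatments
  for (a in tr) for (b in tr) for (c in tr) {
    expect_equal(te[a, b], te[a, c] + te[c, b], tolerance = 1e-10)
  }
})

test_that("updating the network adds precisions for the studied comparison", {
  chain <- chain_data()
  new_trial <- tibble::tibble(studlab = "new", treat1 = "A", treat2 = "B",
                              TE = 0.1, seTE = 0.5)
  upd <- update_network(chain, new_trial)
  expect_equal(upd$se_matrix["A", "B"], 0.5 / sqrt(2), tolerance = 1e-10)

  # a nearly uninformative trial leaves the indirect estimate unchanged
  weak <- dplyr::mutate(new_trial, seTE = 1e5)
  expect_equal(update_network(chain, weak)$se_matrix["A", "B"], 0.5,
               tolerance = 1e-6)

  # precision additivity on random networks and random new records
  set.seed(31)
  for (i in 1:10) {
    dat <- random_network_data(4, n_extra = 2)
    fit <- fit_nma(dat)
    pair <- sample(fit$treatments, 2)
    rec <- tibble::tibble(studlab = "new", treat1 = pair[1],
                          treat2 = pair[2], TE = rnorm(1),
                          seTE = runif(1, 0.1, 1))
    upd <- update_network(dat, rec)
    expect_equal(
      1 / upd$se_matrix[pair[1], pair[2]]^2,
      1 / rec$seTE^2 + 1 / fit$se_matrix[pair[1], pair[2]]^2,
      tolerance = 1e-10
    )
  }

  # cross-module: a new trial with the closed-form trial SE reproduces
  # the pooled design variance
  sig <- indirect_se(chain, "A", "B")
  se_trial <- sqrt(trial_variance(0.2, 0.3, 317, 277))
  upd <- update_network(chain, tibble::tibble(
    studlab = "new", treat1 = "A", treat2 = "B", TE = 0, seTE = se_trial
  ))
  expect_equal(upd$se_matrix["A", "B"]^2,
               combined_variance(trial_variance(0.2, 0.3, 317, 277), sig),
               tolerance = 1e-10)

  expect_error(
    update_network(chain, tibble::tibble(
      studlab = "new", treat1 = "A", treat2 = "Z", TE = 0, seTE = 1)),
    "not in the network"
  )
})

test_that("disconnected networks and absent treatments are rejected", {
  disc <- tibble::tibble(
    studlab = c("s1", "s2"), treat1 = c("A", "C"), treat2 = c("B", "D"),
    TE = 0, seTE = 1
  )
  expect_error(fit_nma(disc), "disconnected")
  expect_error(fit_nma(disc), "A, B")
  expect_error(fit_nma(chain_data(), baseline = "Z"), "baseline")
  expect_error(indirect_se(chain_data(), "A", "Z"), "not in the network")
})

test_that("tidy and glance summarise the fit", {
  fit <- fit_nma(chain_data())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6) # 3 * 2 ordered pairs
  ab <- td[td$treat1 == "A" & td$treat2 == "B", ]
  expect_equal(ab$std.error, 0.5)
  gl <- glance(fit)
  expect_equal(gl$n_treatments, 3)
  expect_equal(gl$n_studies, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
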