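#' Specify a synthetic network of binomial-outcome trials
#'
#' A lightweight specification from which arm-level data can be drawn:
#' per-treatment event risks, a study layout (which treatments each study
#' compares) and per-arm sizes. The comparison graph must be connected and
#' every treatment must appear in at least one study.
#'
#' @param risks Named numeric vector of event risks in (0, 1), one per
#'   treatment.
#' @param studies List of character vectors, one per study, each naming the
#'   (>= 2) treatments compared in that study.
#' @param arm_size Either a single arm size shared by all arms, or a list
#'   parallel to `studies` of per-arm size vectors. All sizes >= 2.
#' @return An object of class `network_spec`.
#' @seealso [generate_network()], [brd_network_spec()]
#' @export
network_spec <- function(risks, studies, arm_size = 150) {
  if (is.null(names(risks)) || any(names(risks) == "")) {
    stop("`risks` must be a named vector", call. = FALSE)
  }
  check_risk(risks, "risks")
  if (!is.list(studies) || length(studies) == 0) {
    stop("`studies` must be a non-empty list of treatment subsets",
         call. = FALSE)
  }
  used <- unique(unlist(studies))
  unknown <- setdiff(used, names(risks))
  if (length(unknown) > 0) {
    stop(sprintf("studies mention treatment(s) without a risk: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  isolated <- setdiff(names(risks), used)
  if (length(isolated) > 0) {
    stop(sprintf("treatment(s) appear in no study: %s",
                 paste(isolated, collapse = ", ")), call. = FALSE)
  }
  if (any(vapply(studies, length, 1L) < 2)) {
    stop("every study must compare at least two treatments", call. = FALSE)
  }
  sizes <- if (is.list(arm_size)) {
    if (length(arm_size) != length(studies)) {
      stop("`arm_size` list must parallel `studies`", call. = FALSE)
    }
    arm_size
  } else {
    lapply(studies, function(s) rep(arm_size, length(s)))
  }
  if (any(unlist(sizes) < 2)) stop("arm sizes must be >= 2", call. = FALSE)
  # connectivity of the comparison graph
  edges <- do.call(rbind, lapply(studies, function(s) {
    t(utils::combn(s, 2))
  }))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = data.frame(name = names(risks)))
  if (igraph::components(g)$no > 1) {
    stop("the specified comparison graph is disconnected", call. = FALSE)
  }
  structure(list(risks = risks, studies = studies, arm_size = sizes),
            class = "network_spec")
}

#' A synthetic network emulating a published respiratory-disease network
#'
#' Builds a `network_spec` with the scale and shape of the Bovine
#' Respiratory Disease (BRD) treatment network commonly used in
#' antibiotic-comparison work: 13 treatments, 98 trials and 204 arms (90
#' two-arm and 8 three-arm trials), with the untreated control (`NAC`)
#' carrying a high event risk (0.68) and the active treatments risks in the
#' 0.15-0.40 range; `CEFTP` (0.1868955) and `TILD` (0.2366667) never meet
#' in a direct comparison, so a planned CEFTP-vs-TILD trial is informed
#' only indirectly. The underlying arm-level data are not public, so the
#' layout and arm sizes here are synthetic stand-ins at a realistic feedlot
#' trial scale (150 animals per arm); only the drawn event counts are
#' random.
#'
#' @param arm_size Animals per arm, default 150.
#' @return A `network_spec`.
#' @export
brd_network_spec <- function(arm_size = 150) {
  risks <- c(
    NAC = 0.68, CEFTP = 0.1868955, TILD = 0.2366667, ENRO = 0.24,
    FLOR = 0.28, TULA = 0.16, GAMI = 0.27, DANO = 0.30, TILM = 0.33,
    OXYT = 0.38, TMS = 0.40, CEFT = 0.22, PENI = 0.36
  )
  actives <- setdiff(names(risks), "NAC")
  studies <- vector("list", 98)
  # 60 placebo-controlled two-arm trials, cycling over the actives
  for (i in 1:60) studies[[i]] <- c("NAC", actives[(i - 1) %% 12 + 1])
  # 30 head-to-head two-arm trials; CEFTP and TILD never share a study
  pairs <- list(
    c("CEFTP", "TULA"), c("TILD", "ENRO"), c("FLOR", "TULA"),
    c("ENRO", "FLOR"), c("GAMI", "TULA"), c("DANO", "TILM"),
    c("OXYT", "TMS"), c("CEFT", "CEFTP"), c("TILD", "TILM"),
    c("PENI", "OXYT"), c("TULA", "TILM"), c("ENRO", "DANO"),
    c("FLOR", "GAMI"), c("CEFT", "TULA"), c("TMS", "PENI")
  )
  for (i in 1:30) studies[[60 + i]] <- pairs[[(i - 1) %% 15 + 1]]
  # 8 three-arm trials including the control
  triples <- list(
    c("NAC", "CEFTP", "TULA"), c("NAC", "TILD", "FLOR"),
    c("NAC", "ENRO", "GAMI"), c("NAC", "DANO", "OXYT"),
    c("NAC", "TILM", "TMS"), c("NAC", "CEFT", "PENI"),
    c("NAC", "TULA", "FLOR"), c("NAC", "ENRO", "TILM")
  )
  for (i in 1:8) studies[[90 + i]] <- triples[[i]]
  network_spec(risks, studies, arm_size)
}

#' Draw arm-level data from a network specification
#'
#' For each arm, draws the event count from `Binomial(n, p)` with the
#' treatment's risk, then derives the contrast-level dataset via
#' [arms_to_contrasts()]. Deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list with `arms` (tibble: `studlab`, `treat`, `r`, `n`) and
#'   `contrasts` (tibble as accepted by [fit_nma()]).
#' @export
generate_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  arms <- tibble::tibble(
    studlab = rep(sprintf("s%03d", seq_along(spec$studies)),
                  vapply(spec$studies, length, 1L)),
    treat = unlist(spec$studies),
    n = unlist(spec$arm_size)
  )
  arms$r <- stats::rbinom(nrow(arms), arms$n, spec$risks[arms$treat])
  arms <- arms[, c("studlab", "treat", "r", "n")]
  list(arms = arms, contrasts = arms_to_contrasts(arms))
}

#' Redraw the event counts of an arm-level dataset
#'
#' Keeps the study layout and arm sizes, replacing every event count with a
#' fresh `Binomial(n, p)` draw at the supplied per-treatment risks. This is
#' the resampling step of the simulation protocols: the simulated existing
#' evidence shares the real network's structure but has known truth.
#'
#' @param arms Arm-level tibble (`studlab`, `treat`, `r`, `n`).
#' @param risks Named risk vector covering every treatment in `arms`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return The arm-level tibble with redrawn `r`.
#' @export
resample_network <- function(arms, risks, seed = NULL) {
  arms <- validate_arms(arms)
  missing <- setdiff(unique(arms$treat), names(risks))
  if (length(missing) > 0) {
    stop(sprintf("no risk supplied for treatment(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_risk(risks, "risks")
  if (!is.null(seed)) set.seed(seed)
  arms$r <- stats::rbinom(nrow(arms), arms$n, risks[arms$treat])
  arms
}

#' Simulate the planned two-arm trial once
#'
#' Draws the two arms' event counts and returns the estimated log odds
#' ratio (of `treat1` relative to `treat2`) with its Wald standard error,
#' equivalent to the logistic-regression estimate; zero cells are handled
#' by the continuity rule of [contrast_from_counts()].
#'
#' @param p1,p2 True event risks of the two arms.
#' @param n1,n2 Arm sizes.
#' @param treat1,treat2 Labels for the contrast row.
#' @param studlab Study label for the contrast row.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A one-row tibble: `studlab`, `treat1`, `treat2`, `TE`, `seTE`,
#'   `corrected`.
#' @export
simulate_new_trial <- function(p1, p2, n1, n2, treat1 = "A", treat2 = "B",
                               studlab = "new", seed = NULL) {
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  if (!is.null(seed)) set.seed(seed)
  r1 <- stats::rbinom(1, n1, p1)
  r2 <- stats::rbinom(1, n2, p2)
  est <- contrast_from_counts(r1, n1, r2, n2)
  tibble::tibble(studlab = studlab, treat1 = treat1, treat2 = treat2,
                 TE = est$TE, seTE = est$seTE, corrected = est$corrected)
}

# Precomputed fitting machinery for the simulation loops. The study
# layout, the design matrix and the contrast vector of the planned
# comparison are fixed across replicates; only event counts change. The
# new trial enters the normal equations as a rank-one update, which is
# algebraically identical to refitting the enlarged network (verified
# against fit_nma()/update_network() in the test suite).
make_network_engine <- function(arms, treat1, treat2) {
  arms <- validate_arms(arms)
  rows_by_study <- split(seq_len(nrow(arms)), arms$studlab)
  idx <- lapply(rows_by_study, function(rows) {
    if (length(rows) < 2) {
      stop("study has a single arm and yields no contrast", call. = FALSE)
    }
    pairs <- utils::combn(length(rows), 2)
    cbind(rows[pairs[1, ]], rows[pairs[2, ]])
  })
  idx <- do.call(rbind, idx)
  ct1 <- arms$treat[idx[, 1]]
  ct2 <- arms$treat[idx[, 2]]
  treatments <- sort(unique(arms$treat))
  basic <- treatments[-1]
  contrast_row <- function(t1, t2) {
    x <- stats::setNames(numeric(length(basic)), basic)
    if (t1 %in% basic) x[t1] <- 1
    if (t2 %in% basic) x[t2] <- x[t2] - 1
    x
  }
  X <- t(vapply(seq_along(ct1), function(i) contrast_row(ct1[i], ct2[i]),
                numeric(length(basic))))
  # connectivity checked once, on the template layout
  check_connected(
    tibble::tibble(studlab = arms$studlab[idx[, 1]], treat1 = ct1,
                   treat2 = ct2, TE = 0, seTE = 1),
    treatments
  )
  list(arms = arms, i1 = idx[, 1], i2 = idx[, 2], X = X,
       x_pair = contrast_row(treat1, treat2))
}

# WLS fit of the engine's network for one replicate's event counts;
# returns the pieces needed for the pair SE and the rank-one update.
engine_fit <- function(eng, r) {
  cc <- contrast_from_counts(r[eng$i1], eng$arms$n[eng$i1],
                             r[eng$i2], eng$arms$n[eng$i2])
  w <- 1 / cc$seTE^2
  XtWX <- crossprod(eng$X, eng$X * w)
  XtWy <- crossprod(eng$X, cc$TE * w)
  V <- chol2inv(chol(XtWX))
  x <- eng$x_pair
  list(XtWX = XtWX, XtWy = XtWy,
       sigma_pair = sqrt(drop(x %*% V %*% x)))
}

# simulate the new trial at an allocation and test the comparison alone
# and within the updated network
analyse_replicate <- function(eng, fit, p1, p2, n1, n2, z_crit) {
  r1 <- stats::rbinom(1, n1, p1)
  r2 <- stats::rbinom(1, n2, p2)
  est <- contrast_from_counts(r1, n1, r2, n2)
  w_n <- 1 / est$seTE^2
  x <- eng$x_pair
  M <- fit$XtWX + w_n * tcrossprod(x)
  V <- chol2inv(chol(M))
  mu <- V %*% (fit$XtWy + w_n * est$TE * x)
  se_w <- sqrt(drop(x %*% V %*% x))
  te_w <- drop(x %*% mu)
  list(
    ind_wo = abs(est$TE / est$seTE) > z_crit,
    ind_w = abs(te_w / se_w) > z_crit,
    se_wo = est$seTE,
    se_w = se_w,
    corrected = est$corrected
  )
}

check_no_direct_edge <- function(arms, treat1, treat2) {
  both <- tapply(arms$treat, arms$studlab,
                 function(tr) all(c(treat1, treat2) %in% tr))
  if (any(both)) {
    stop(sprintf(paste0("treatments '%s' and '%s' already have a direct ",
                        "comparison in the network"), treat1, treat2),
         call. = FALSE)
  }
  invisible(TRUE)
}

sim_risks <- function(arms, risks, treat1, treat2, lor) {
  missing <- setdiff(unique(arms$treat), names(risks))
  if (length(missing) > 0) {
    stop(sprintf("no risk supplied for treatment(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  p1 <- unname(risks[[treat1]])
  p2 <- risk_from_lor(p1, -lor) # lor is treat2 relative to treat1
  risks[[treat2]] <- p2
  list(risks = risks, p1 = p1, p2 = p2)
}

#' Validate the fixed-total design by Monte-Carlo simulation
#'
#' The first simulation protocol: a planned trial between two treatments
#' that are in the network but share no direct comparison is simulated at a
#' fixed total sample size under two allocation strategies (the
#' variance-minimising split and the even split). Each replicate (i)
#' redraws the existing network's event counts at the known risks, (ii)
#' fits the fixed-effect NMA to obtain the replicate's indirect standard
#' error, (iii) draws the new trial, and (iv) tests the comparison at level
#' `sig.level` both in isolation and within the updated network. Simulated
#' rejection rates and average standard errors are reported next to their
#' closed-form counterparts, which they should match up to Monte-Carlo
#' error.
#'
#' The risk of `treat2` is recomputed from the risk of `treat1` and the
#' design effect size `lor` (log odds ratio of `treat2` relative to
#' `treat1`), so the supplied `risks[treat2]` (if any) is ignored.
#'
#' @param arms Template arm-level data of the existing network (e.g. from
#'   [generate_network()]); only its layout and arm sizes are reused.
#' @param risks Named per-treatment risk vector (the simulation truth).
#' @param treat1,treat2 The planned trial's treatments (no direct edge).
#' @param lor Design effect size on the log odds ratio scale.
#' @param n_total Fixed total sample size of the new trial.
#' @param n_reps Number of replicates, default 2000.
#' @param sig.level Two-sided significance level, default 0.05.
#' @param seed Root seed; each replicate gets a derived child seed, so
#'   results are fully reproducible and both allocation strategies see the
#'   same resampled network within a replicate.
#' @return A tibble with one row per allocation x analysis method:
#'   `allocation`, `method`, `n1`, `n2`, `sim_power`, `formula_power`,
#'   `sim_se`, `formula_se`, `zero_cell_rate`, `n_reps`.
#' @export
simulate_design_fixed_total <- function(arms, risks, treat1, treat2, lor,
                                        n_total, n_reps = 2000,
                                        sig.level = 0.05, seed = 1) {
  arms <- validate_arms(arms)
  check_no_direct_edge(arms, treat1, treat2)
  rk <- sim_risks(arms, risks, treat1, treat2, lor)
  z_crit <- stats::qnorm(1 - sig.level / 2)
  allocs <- list(
    optimal = optimal_split(rk$p1, rk$p2, n_total),
    even = c(n1 = floor(n_total / 2), n2 = ceiling(n_total / 2))
  )
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  acc <- array(0, dim = c(2, 8), dimnames = list(
    names(allocs),
    c("ind_wo", "ind_w", "se_wo", "se_w", "fpow_w", "fse_w", "corrected",
      "n")
  ))
  v_trial <- vapply(allocs, function(al)
    trial_variance(rk$p1, rk$p2, al["n1"], al["n2"]), 0)
  fpow_wo <- lor_power(lor, sqrt(v_trial), sig.level)
  eng <- make_network_engine(arms, treat1, treat2)
  p_arm <- rk$risks[arms$treat]
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    fit <- engine_fit(eng, stats::rbinom(nrow(arms), arms$n, p_arm))
    sigma_e <- fit$sigma_pair
    for (k in seq_along(allocs)) {
      al <- allocs[[k]]
      res <- analyse_replicate(eng, fit, rk$p1, rk$p2, al[["n1"]],
                               al[["n2"]], z_crit)
      v_w <- combined_variance(v_trial[k], sigma_e)
      acc[k, ] <- acc[k, ] + c(res$ind_wo, res$ind_w, res$se_wo, res$se_w,
                               lor_power(lor, sqrt(v_w), sig.level),
                               sqrt(v_w), res$corrected, 1)
    }
  }
  out <- lapply(seq_along(allocs), function(k) {
    m <- acc[k, ] / n_reps
    tibble::tibble(
      allocation = rep(names(allocs)[k], 2),
      method = c("with", "without"),
      n1 = allocs[[k]][["n1"]], n2 = allocs[[k]][["n2"]],
      sim_power = c(m[["ind_w"]], m[["ind_wo"]]),
      formula_power = c(m[["fpow_w"]], unname(fpow_wo[k])),
      sim_se = c(m[["se_w"]], m[["se_wo"]]),
      formula_se = c(m[["fse_w"]], sqrt(unname(v_trial[k]))),
      zero_cell_rate = m[["corrected"]],
      n_reps = n_reps
    )
  })
  dplyr::bind_rows(out)
}

#' Validate the target-power design by Monte-Carlo simulation
#'
#' The second simulation protocol: per replicate, the existing network is
#' redrawn and the minimum-sample-size problem is solved for the
#' with-network analysis at the replicate's indirect standard error, under
#' both the uneven (variance-minimising) and even allocation constraints.
#' The new trial is then simulated at the solved sizes and analysed with
#' and without the network. The with-network rejection rate should sit at
#' the target power; the reported mean sample sizes show how much the two
#' allocation constraints differ in practice.
#'
#' @inheritParams simulate_design_fixed_total
#' @param power.level Target power for the with-network analysis.
#' @return A tibble with one row per allocation x analysis method:
#'   `allocation`, `method`, `mean_n1`, `mean_n2`, `mean_total`,
#'   `sim_power`, `formula_power`, `sim_se`, `formula_se`,
#'   `zero_cell_rate`, `n_reps`.
#' @export
simulate_design_target_power <- function(arms, risks, treat1, treat2, lor,
                                         power.level = 0.8, n_reps = 2000,
                                         sig.level = 0.05, seed = 1) {
  arms <- validate_arms(arms)
  check_no_direct_edge(arms, treat1, treat2)
  rk <- sim_risks(arms, risks, treat1, treat2, lor)
  if (lor == 0) stop("`lor` must be nonzero in target-power mode",
                     call. = FALSE)
  z_crit <- stats::qnorm(1 - sig.level / 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  alloc_names <- c("optimal", "even")
  acc <- array(0, dim = c(2, 11), dimnames = list(
    alloc_names,
    c("ind_wo", "ind_w", "se_wo", "se_w", "fpow_w", "fpow_wo", "fse_w",
      "fse_wo", "n1", "n2", "corrected")
  ))
  eng <- make_network_engine(arms, treat1, treat2)
  p_arm <- rk$risks[arms$treat]
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    fit <- engine_fit(eng, stats::rbinom(nrow(arms), arms$n, p_arm))
    sigma_e <- fit$sigma_pair
    sols <- list(
      optimal = ssnma(rk$p1, rk$p2, sigma_e, power.level, sig.level,
                      method = "with", allocation = "uneven"),
      even = ssnma(rk$p1, rk$p2, sigma_e, power.level, sig.level,
                   method = "with", allocation = "even")
    )
    for (k in 1:2) {
      sol <- sols[[k]]
      res <- analyse_replicate(eng, fit, rk$p1, rk$p2, sol$n1, sol$n2,
                               z_crit)
      v_t <- trial_variance(rk$p1, rk$p2, sol$n1, sol$n2)
      v_w <- combined_variance(v_t, sigma_e)
      acc[k, ] <- acc[k, ] + c(res$ind_wo, res$ind_w, res$se_wo, res$se_w,
                               lor_power(lor, sqrt(v_w), sig.level),
                               lor_power(lor, sqrt(v_t), sig.level),
                               sqrt(v_w), sqrt(v_t), sol$n1, sol$n2,
                               res$corrected)
    }
  }
  out <- lapply(1:2, function(k) {
    m <- acc[k, ] / n_reps
    tibble::tibble(
      allocation = rep(alloc_names[k], 2),
      method = c("with", "without"),
      mean_n1 = m[["n1"]], mean_n2 = m[["n2"]],
      mean_total = m[["n1"]] + m[["n2"]],
      sim_power = c(m[["ind_w"]], m[["ind_wo"]]),
      formula_power = c(m[["fpow_w"]], m[["fpow_wo"]]),
      sim_se = c(m[["se_w"]], m[["se_wo"]]),
      formula_se = c(m[["fse_w"]], m[["fse_wo"]]),
      zero_cell_rate = m[["corrected"]],
      n_reps = n_reps
    )
  })
  dplyr::bind_rows(out)
}

#' Run a simulation scenario described by a configuration file
#'
#' Reads a flat JSON configuration (or an equivalent list) describing the
#' synthetic network and the scenario, builds the network, and dispatches
#' to [simulate_design_fixed_total()] or
#' [simulate_design_target_power()]. Required fields: `treatments` (named
#' risks), `studies` (list of treatment subsets), `treat1`, `treat2`,
#' `lor`, `n_reps`, `seed`, and either `n_total` (fixed-total mode) or
#' `power_level` (target-power mode). Optional: `arm_size` (default 150),
#' `sig_level` (default 0.05).
#'
#' @param config Path to a JSON file, or a list with the fields above.
#' @return The tidy simulation summary tibble.
#' @export
simulate_scenario <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config$studies <- normalise_studies(config$studies)
  needed <- c("treatments", "studies", "treat1", "treat2", "lor",
              "n_reps", "seed")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0) {
    stop(sprintf("config is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  risks <- unlist(config$treatments)
  spec <- network_spec(risks, lapply(config$studies, as.character),
                       config$arm_size %||% 150)
  net <- generate_network(spec, seed = config$seed)
  sig <- config$sig_level %||% 0.05
  if (!is.null(config$n_total)) {
    simulate_design_fixed_total(net$arms, risks, config$treat1,
                                config$treat2, config$lor, config$n_total,
                                n_reps = config$n_reps, sig.level = sig,
                                seed = config$seed)
  } else if (!is.null(config$power_level)) {
    simulate_design_target_power(net$arms, risks, config$treat1,
                                 config$treat2, config$lor,
                                 power.level = config$power_level,
                                 n_reps = config$n_reps, sig.level = sig,
                                 seed = config$seed)
  } else {
    stop("config must contain either `n_total` or `power_level`",
         call. = FALSE)
  }
}

# JSON study layouts arrive as a matrix (equal arm counts), a data frame,
# or a list; normalise to a list of character vectors.
normalise_studies <- function(studies) {
  if (is.matrix(studies)) {
    studies <- asplit(studies, 1)
  } else if (is.data.frame(studies)) {
    studies <- asplit(as.matrix(studies), 1)
  }
  lapply(studies, function(s) as.character(unlist(s)))
}
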