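#' Variance-minimising integer split of a fixed total sample size
#'
#' For a two-arm binomial trial the variance of the estimated log odds
#' ratio is `a/n1 + b/n2` with `a = 1/(p1 q1)`, `b = 1/(p2 q2)`. Subject
#' to `n1 + n2 = N` the continuous optimum is
#' `n1* = N sqrt(a) / (sqrt(a) + sqrt(b))`; the integer solution is
#' whichever of its floor and ceiling (complement adjusted) gives the
#' smaller variance, which coincides with exhaustive search because the
#' variance is convex in `n1`.
#'
#' @inheritParams trial_variance
#' @param N Total sample size (integer, >= 2).
#' @return A named integer vector `c(n1 = , n2 = )`.
#' @examples
#' optimal_split(0.2, 0.3, 200) # 107 / 93
#' @export
optimal_split <- function(p1, p2, N) {
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  if (length(N) != 1 || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  best_split(1 / (p1 * (1 - p1)), 1 / (p2 * (1 - p2)), N)
}

# Integer minimiser of a/n1 + b/(N - n1); ties assign the extra subject to
# the arm with the larger per-subject variance contribution (larger of a, b;
# a-arm wins exact ties).
best_split <- function(a, b, N) {
  cont <- N * sqrt(a) / (sqrt(a) + sqrt(b))
  cand <- unique(pmin(pmax(c(floor(cont), ceiling(cont)), 1), N - 1))
  v <- a / cand + b / (N - cand)
  eps <- 1e-12 * min(v)
  tied <- v <= min(v) + eps
  pick <- if (sum(tied) > 1) {
    if (a >= b) max(cand[tied]) else min(cand[tied])
  } else cand[which.min(v)]
  c(n1 = as.integer(pick), n2 = as.integer(N - pick))
}

new_design_solution <- function(n1, n2, power, sd, method, allocation,
                                inputs, degenerate = FALSE) {
  structure(
    list(n1 = as.integer(unname(n1)), n2 = as.integer(unname(n2)),
         power = unname(power), sd = unname(sd), method = method,
         allocation = allocation, inputs = inputs, degenerate = degenerate),
    class = "design_solution"
  )
}

#' Tidy a design solution
#'
#' @param x A `design_solution` from [ssnma()] or [ssanma()].
#' @param ... Unused.
#' @return A one-row tibble with the allocation, achieved power, design
#'   standard deviation and the problem inputs.
#' @export
tidy.design_solution <- function(x, ...) {
  tibble::tibble(
    n1 = x$n1, n2 = x$n2, total = x$n1 + x$n2,
    power = x$power, sd = x$sd,
    method = x$method, allocation = x$allocation,
    p1 = x$inputs$p1, p2 = x$inputs$p2,
    enma_sigma = x$inputs$enma_sigma %||% NA_real_,
    sig.level = x$inputs$sig.level
  )
}

#' @export
glance.design_solution <- function(x, ...) tidy(x, ...)

#' Minimum total sample size to reach a target power
#'
#' Solves the constrained design problem: minimise `n1 + n2` subject to
#' the two-sided power of the planned comparison reaching `power.level`,
#' with the trial analysed either jointly with the existing network
#' (`method = "with"`, pooling precisions with the indirect estimate whose
#' standard error is `enma_sigma`) or in isolation (`"without"`).
#'
#' The required design standard deviation is obtained by root-finding on
#' the full two-term power formula; when `method = "with"` the network
#' precision `1/enma_sigma^2` is subtracted to give the precision the trial
#' itself must supply. The continuous Lagrange solution
#' `n1* = sqrt(a)(sqrt(a) + sqrt(b)) / v` (with `v` the required trial
#' variance) is then rounded:
#'
#' * `rounding = "ceiling"` (default): each group is rounded up. This is
#'   the conventional, guaranteed-conservative rule (at most one extra
#'   subject per arm above the exact optimum) and the one whose results
#'   this package prints by default.
#' * `rounding = "minimal"`: the exact smallest integer total is found by
#'   scanning totals upward from the continuous bound, certifying that no
#'   smaller total attains the target. This can undercut `"ceiling"` by one
#'   subject in one arm.
#'
#' With `allocation = "even"` both groups get
#' `ceiling((a + b) / v)` subjects, which is exactly minimal among even
#' splits. If the network alone already attains the target power
#' (`method = "with"` and required trial precision <= 0) the degenerate
#' minimum allocation (1, 1) is returned with a warning and flagged in the
#' result.
#'
#' @inheritParams design_sd
#' @param power.level Target power, in (`sig.level`, 1).
#' @param sig.level Two-sided significance level, default 0.05.
#' @param allocation `"uneven"` (variance-minimising split, default) or
#'   `"even"` (equal groups).
#' @param rounding `"ceiling"` (default) or `"minimal"`, see Details.
#' @return A `design_solution`; print it for the sample sizes and power,
#'   or pass it to [tidy()] for a one-row tibble.
#' @examples
#' ssnma(p1 = 0.2, p2 = 0.3, enma_sigma = 0.3, power.level = 0.8,
#'       method = "with", allocation = "uneven") # 187 / 163, power 0.801
#' @export
ssnma <- function(p1, p2, enma_sigma = NULL, power.level = 0.8,
                  sig.level = 0.05, method = c("with", "without"),
                  allocation = c("uneven", "even"),
                  rounding = c("ceiling", "minimal")) {
  method <- match.arg(method)
  allocation <- match.arg(allocation)
  rounding <- match.arg(rounding)
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  check_prob(sig.level, "sig.level")
  if (power.level <= sig.level || power.level >= 1) {
    stop("`power.level` must lie in (sig.level, 1)", call. = FALSE)
  }
  lor <- lor_from_risks(p1, p2)
  if (lor == 0) {
    stop("infeasible: p1 = p2 implies a zero log odds ratio, so no sample ",
         "size attains the target power", call. = FALSE)
  }
  if (method == "with" && is.null(enma_sigma)) {
    stop("`enma_sigma` is required when method = \"with\"", call. = FALSE)
  }
  inputs <- list(p1 = p1, p2 = p2, enma_sigma = enma_sigma,
                 power.level = power.level, sig.level = sig.level)
  a <- 1 / (p1 * (1 - p1))
  b <- 1 / (p2 * (1 - p2))
  v_total <- required_sd(lor, power.level, sig.level)^2
  prec_trial <- 1 / v_total - if (method == "with") 1 / enma_sigma^2 else 0
  if (prec_trial <= 0) {
    warning("the existing network alone already attains the target power; ",
            "returning the minimum allocation (1, 1)", call. = FALSE)
    sd <- design_sd(p1, p2, 1, 1, enma_sigma, method)
    return(new_design_solution(1L, 1L, lor_power(lor, sd, sig.level), sd,
                               method, allocation, inputs, degenerate = TRUE))
  }
  v_trial <- 1 / prec_trial
  feasible <- function(n1, n2) {
    lor_power(lor, design_sd(p1, p2, n1, n2, enma_sigma, method),
              sig.level) >= power.level
  }
  if (allocation == "even") {
    n <- ceiling((a + b) / v_trial)
    sol <- c(n1 = n, n2 = n)
  } else if (rounding == "ceiling") {
    sol <- c(n1 = ceiling(sqrt(a) * (sqrt(a) + sqrt(b)) / v_trial),
             n2 = ceiling(sqrt(b) * (sqrt(a) + sqrt(b)) / v_trial))
  } else {
    # exact minimum: the best split at total m has variance >=
    # (sqrt(a)+sqrt(b))^2 / m, so scan totals up from that bound
    m <- max(2, ceiling((sqrt(a) + sqrt(b))^2 / v_trial) - 1)
    repeat {
      cand <- best_split(a, b, m)
      if (feasible(cand["n1"], cand["n2"])) { sol <- cand; break }
      m <- m + 1
    }
  }
  stopifnot(feasible(sol["n1"], sol["n2"]))
  sd <- design_sd(p1, p2, sol["n1"], sol["n2"], enma_sigma, method)
  new_design_solution(sol["n1"], sol["n2"],
                      lor_power(lor, sd, sig.level), unname(sd),
                      method, allocation, inputs)
}

#' Power-maximising allocation of a fixed total sample size
#'
#' Splits a fixed total `N` between the two arms to maximise the power of
#' the planned comparison. Because pooling with the network adds a constant
#' precision, the optimal split does not depend on `method`; only the
#' achieved power does.
#'
#' @inheritParams ssnma
#' @param N Total sample size to allocate (integer >= 2; must be even when
#'   `allocation = "even"`).
#' @return A `design_solution` with `n1 + n2 = N`.
#' @examples
#' ssanma(p1 = 0.2, p2 = 0.3, enma_sigma = 0.3, N = 200,
#'        method = "with") # 107 / 93, power 0.679
#' @export
ssanma <- function(p1, p2, enma_sigma = NULL, N, sig.level = 0.05,
                   method = c("with", "without"),
                   allocation = c("uneven", "even")) {
  method <- match.arg(method)
  allocation <- match.arg(allocation)
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  check_prob(sig.level, "sig.level")
  if (length(N) != 1 || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  if (method == "with" && is.null(enma_sigma)) {
    stop("`enma_sigma` is required when method = \"with\"", call. = FALSE)
  }
  if (allocation == "even") {
    if (N %% 2 != 0) {
      stop("even allocation of an odd total is unsatisfiable; ",
           "choose an even `N` or allocation = \"uneven\"", call. = FALSE)
    }
    sol <- c(n1 = N / 2, n2 = N / 2)
  } else {
    sol <- optimal_split(p1, p2, N)
  }
  sd <- design_sd(p1, p2, sol["n1"], sol["n2"], enma_sigma, method)
  pw <- lor_power(lor_from_risks(p1, p2), sd, sig.level)
  out <- new_design_solution(sol["n1"], sol["n2"], pw, unname(sd), method,
                             allocation,
                             list(p1 = p1, p2 = p2, enma_sigma = enma_sigma,
                                  N = N, sig.level = sig.level))
  out
}

#' @export
print.design_solution <- function(x, ...) {
  label <- if (!is.null(x$inputs$N)) "$sample_alloc" else "$sample_size"
  cat(label, "\n", sep = "")
  cat("[1]", x$n1, x$n2, "\n")
  cat("$power\n")
  cat("[1]", round(x$power, 3), "\n")
  if (x$degenerate) {
    cat("(existing network alone already attains the target power)\n")
  }
  invisible(x)
}

#' Brute-force grid search over integer allocations
#'
#' Exhaustive enumeration of integer allocations, intended as an
#' independent verifier for [ssnma()] and [ssanma()]. For
#' `objective = "min_total_at_power"` it scans totals upward from 2,
#' evaluating the power formula at every split of every total, and returns
#' the first feasible allocation (smallest total; among splits of that
#' total the one with maximal power, ties resolved as in [optimal_split()]).
#' For `objective = "max_power_at_N"` it evaluates all `N - 1` splits.
#'
#' @inheritParams ssnma
#' @param objective `"min_total_at_power"` or `"max_power_at_N"`.
#' @param power.level Target power (first objective).
#' @param N Fixed total (second objective).
#' @param allocation `"uneven"` enumerates all splits; `"even"` only equal
#'   ones.
#' @param max_total Search bound for the first objective (error if no
#'   feasible allocation exists below it).
#' @return A `design_solution`.
#' @export
grid_design <- function(p1, p2, enma_sigma = NULL,
                        objective = c("min_total_at_power", "max_power_at_N"),
                        power.level = 0.8, N = NULL, sig.level = 0.05,
                        method = c("with", "without"),
                        allocation = c("uneven", "even"),
                        max_total = 5000) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  allocation <- match.arg(allocation)
  lor <- lor_from_risks(p1, p2)
  a <- 1 / (p1 * (1 - p1))
  b <- 1 / (p2 * (1 - p2))
  pow_at <- function(n1, n2) {
    v <- a / n1 + b / n2
    if (method == "with") v <- combined_variance(v, enma_sigma)
    lor_power(lor, sqrt(v), sig.level)
  }
  inputs <- list(p1 = p1, p2 = p2, enma_sigma = enma_sigma,
                 sig.level = sig.level, N = N)
  # power is a strictly decreasing transform of the trial variance, so the
  # best split is the variance-minimising one; selecting on the variance
  # avoids spurious ties where the power saturates in floating point
  pick_best <- function(n1, m) {
    v <- a / n1 + b / (m - n1)
    eps <- 1e-12 * min(v)
    tied <- v <= min(v) + eps
    if (sum(tied) > 1) {
      if (a >= b) max(n1[tied]) else min(n1[tied])
    } else n1[which.min(v)]
  }
  if (objective == "max_power_at_N") {
    stopifnot(!is.null(N))
    n1 <- if (allocation == "even") N / 2 else seq_len(N - 1)
    pick <- pick_best(n1, N)
    return(new_design_solution(pick, N - pick, pow_at(pick, N - pick),
                               sqrt_design_var(a, b, pick, N - pick,
                                               enma_sigma, method),
                               method, allocation, inputs))
  }
  for (m in 2:max_total) {
    n1 <- if (allocation == "even") {
      if (m %% 2 != 0) next else m / 2
    } else seq_len(m - 1)
    ok <- pow_at(n1, m - n1) >= power.level
    if (any(ok)) {
      pick <- pick_best(n1[ok], m)
      return(new_design_solution(pick, m - pick, pow_at(pick, m - pick),
                                 sqrt_design_var(a, b, pick, m - pick,
                                                 enma_sigma, method),
                                 method, allocation, inputs))
    }
  }
  stop("no feasible allocation with total <= max_total", call. = FALSE)
}

sqrt_design_var <- function(a, b, n1, n2, enma_sigma, method) {
  v <- a / n1 + b / n2
  if (method == "with") v <- combined_variance(v, enma_sigma)
  sqrt(v)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
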