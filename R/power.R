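#' Log odds ratio implied by two event risks
#'
#' Converts the event risks of the two arms of a planned trial into the log
#' odds ratio of treatment 2 relative to treatment 1, the effect scale on
#' which all power and sample-size computations in this package operate.
#'
#' @param p1,p2 Event risks in (0, 1). Vectorised.
#' @return `log-odds(p2) - log-odds(p1)`, a numeric vector.
#' @examples
#' lor_from_risks(0.2, 0.3)
#' @seealso [risk_from_lor()] for the inverse mapping.
#' @export
lor_from_risks <- function(p1, p2) {
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  stats::qlogis(p2) - stats::qlogis(p1)
}

#' Event risk of a treatment given a reference risk and a log odds ratio
#'
#' Inverts [lor_from_risks()]: given the risk of a reference treatment and
#' the log odds ratio of the *reference relative to the target*, returns the
#' target treatment's risk. This is the conversion used to derive the risk
#' of the second arm from a network estimate anchored at a baseline
#' treatment whose absolute risk is known.
#'
#' @param p_ref Risk of the reference treatment, in (0, 1).
#' @param lor Log odds ratio of the reference treatment relative to the
#'   target (i.e. `log-odds(ref) - log-odds(target)`).
#' @return The target risk `p_ref / (p_ref + exp(lor) * (1 - p_ref))`.
#' @examples
#' risk_from_lor(0.1876, -0.299) # ~ 0.2374
#' @export
risk_from_lor <- function(p_ref, lor) {
  check_risk(p_ref, "p_ref")
  p_ref / (p_ref + exp(lor) * (1 - p_ref))
}

#' Variance of the log odds ratio estimated from the new trial alone
#'
#' The large-sample (Wald / logistic-regression) variance of the estimated
#' log odds ratio from a two-arm binomial trial,
#' `1/(n1 p1 q1) + 1/(n2 p2 q2)` with `q = 1 - p`.
#'
#' @inheritParams lor_from_risks
#' @param n1,n2 Arm sizes (positive). Vectorised.
#' @return The variance, a numeric vector.
#' @export
trial_variance <- function(p1, p2, n1, n2) {
  check_risk(p1, "p1")
  check_risk(p2, "p2")
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("arm sizes `n1` and `n2` must be positive", call. = FALSE)
  }
  1 / (n1 * p1 * (1 - p1)) + 1 / (n2 * p2 * (1 - p2))
}

#' Variance of the comparison after pooling the trial with the network
#'
#' Precision (inverse variance) of the updated estimate is the sum of the
#' trial precision and the existing-network precision, so the pooled
#' variance is the harmonic combination
#' `(1/var_trial + 1/enma_sigma^2)^-1`.
#'
#' @param var_trial Variance of the trial-only estimate (> 0).
#' @param enma_sigma Standard error of the indirect estimate for the same
#'   comparison from the existing network (> 0).
#' @return The pooled variance, always smaller than either component.
#' @export
combined_variance <- function(var_trial, enma_sigma) {
  if (any(var_trial <= 0)) stop("`var_trial` must be > 0", call. = FALSE)
  if (any(enma_sigma <= 0)) stop("`enma_sigma` must be > 0", call. = FALSE)
  1 / (1 / var_trial + 1 / enma_sigma^2)
}

#' Two-sided power of the Wald test for a log odds ratio
#'
#' Normal-approximation power of the two-sided level-`sig.level` test of
#' `lor = 0`:
#' `Phi(lor/sd - z) + Phi(-lor/sd - z)` with `z = qnorm(1 - sig.level/2)`.
#' At `lor = 0` this equals `sig.level` exactly (the type-I error).
#'
#' @param lor True log odds ratio under the alternative.
#' @param sd Standard deviation of the estimator (> 0).
#' @param sig.level Two-sided significance level, default 0.05.
#' @return Power in (0, 1). Vectorised over `lor` and `sd`.
#' @export
lor_power <- function(lor, sd, sig.level = 0.05) {
  if (any(sd <= 0)) stop("`sd` must be > 0", call. = FALSE)
  check_prob(sig.level, "sig.level")
  z <- stats::qnorm(1 - sig.level / 2)
  stats::pnorm(lor / sd - z) + stats::pnorm(-lor / sd - z)
}

#' Design standard deviation of the estimated log odds ratio
#'
#' The standard deviation entering the power formula, under either analysis
#' plan: `method = "without"` uses the trial-only variance; `method =
#' "with"` pools the trial with the existing network's indirect estimate,
#' whose standard error is `enma_sigma`.
#'
#' @inheritParams trial_variance
#' @param enma_sigma Standard error of the existing-network estimate for
#'   this comparison; required when `method = "with"`.
#' @param method `"with"` (analyse jointly with the network, the default)
#'   or `"without"` (analyse the trial in isolation).
#' @return The standard deviation, a numeric vector.
#' @export
design_sd <- function(p1, p2, n1, n2, enma_sigma = NULL,
                      method = c("with", "without")) {
  method <- match.arg(method)
  v <- trial_variance(p1, p2, n1, n2)
  if (method == "with") {
    if (is.null(enma_sigma)) {
      stop("`enma_sigma` is required when method = \"with\"", call. = FALSE)
    }
    v <- combined_variance(v, enma_sigma)
  }
  sqrt(v)
}

#' Power of the planned trial at a given allocation
#'
#' Convenience wrapper combining [lor_from_risks()], [design_sd()] and
#' [lor_power()].
#'
#' @inheritParams design_sd
#' @inheritParams lor_power
#' @return Power in (0, 1).
#' @examples
#' design_power(0.2, 0.3, 317, 277, method = "without") # ~ 0.801
#' @export
design_power <- function(p1, p2, n1, n2, enma_sigma = NULL,
                         method = c("with", "without"), sig.level = 0.05) {
  method <- match.arg(method)
  lor_power(lor_from_risks(p1, p2),
            design_sd(p1, p2, n1, n2, enma_sigma, method),
            sig.level)
}

# Standard deviation at which the two-sided test attains `power.level`.
# lor_power() is strictly decreasing in sd for lor != 0, so the root is
# unique; solved by bisection (uniroot) to ~1e-12.
required_sd <- function(lor, power.level, sig.level = 0.05) {
  lor <- abs(lor)
  if (lor == 0) stop("target power is unattainable at lor = 0", call. = FALSE)
  upper <- lor
  while (lor_power(lor, upper, sig.level) > power.level) upper <- upper * 2
  lower <- lor / 1e6
  while (lor_power(lor, lower, sig.level) < power.level) lower <- lower / 2
  stats::uniroot(function(s) lor_power(lor, s, sig.level) - power.level,
                 c(lower, upper), tol = 1e-12)$root
}

check_risk <- function(p, name) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(p)
}

check_prob <- function(p, name) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    stop(sprintf("`%s` must be a single number in (0, 1)", name),
         call. = FALSE)
  }
  invisible(p)
}
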