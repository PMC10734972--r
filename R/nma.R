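#' Design matrix of the fixed-effect network meta-analysis
#'
#' Maps every contrast row to a linear combination of the basic parameters
#' (the log odds ratios of each non-baseline treatment versus the
#' baseline). A row comparing treatment `i` with the baseline carries +1 in
#' column `i` (or -1 when the baseline is `treat1`); a row comparing two
#' non-baseline treatments carries +1 in the `treat1` column and -1 in the
#' `treat2` column, as dictated by the consistency assumption.
#'
#' @param data Contrast-level data (see [read_contrasts()]).
#' @param baseline Baseline treatment label; defaults to the
#'   lexicographically smallest label. Results of [fit_nma()] are invariant
#'   to this choice.
#' @return A list with `X` (design matrix, one row per contrast, columns
#'   named by the non-baseline treatments in sorted order), `y` (the `TE`
#'   vector) and `weights` (`1/seTE^2`).
#' @export
nma_design_matrix <- function(data, baseline = NULL) {
  data <- validate_contrasts(data)
  treatments <- sort(unique(c(data$treat1, data$treat2)))
  if (is.null(baseline)) baseline <- treatments[1]
  if (!baseline %in% treatments) {
    stop(sprintf("baseline treatment '%s' does not appear in the data",
                 baseline), call. = FALSE)
  }
  check_connected(data, treatments)
  basic <- setdiff(treatments, baseline)
  X <- matrix(0, nrow = nrow(data), ncol = length(basic),
              dimnames = list(NULL, basic))
  i1 <- match(data$treat1, basic)
  i2 <- match(data$treat2, basic)
  rows <- seq_len(nrow(data))
  ok1 <- !is.na(i1)
  ok2 <- !is.na(i2)
  X[cbind(rows[ok1], i1[ok1])] <- 1
  X[cbind(rows[ok2], i2[ok2])] <- X[cbind(rows[ok2], i2[ok2])] - 1
  list(X = X, y = data$TE, weights = 1 / data$seTE^2)
}

#' Fit a fixed-effect network meta-analysis
#'
#' Weighted least-squares fit of the contrast-based fixed-effect model: the
#' basic parameters are `mu = (X' S^-1 X)^-1 X' S^-1 y` with covariance
#' `(X' S^-1 X)^-1`, where `S` is the diagonal matrix of squared standard
#' errors. Within-study covariance of multi-arm contrasts is not modelled
#' (`S` is fully diagonal). All pairwise effects and standard errors are
#' derived from the basic parameters under the consistency assumption, so
#' the returned matrices are baseline-invariant.
#'
#' @inheritParams nma_design_matrix
#' @return An object of class `nma_fit`: a list with `baseline`,
#'   `treatments`, `basic_estimates`, `basic_cov`, `te_matrix` (pairwise
#'   log odds ratios, row treatment relative to column treatment),
#'   `se_matrix`, `n_studies`, `n_contrasts` and the input `data`.
#' @examples
#' chain <- tibble::tibble(
#'   studlab = c("s1", "s2"), treat1 = c("A", "C"), treat2 = c("C", "B"),
#'   TE = c(0.4, 0.2), seTE = c(0.3, 0.4)
#' )
#' fit <- fit_nma(chain)
#' indirect_se(fit, "A", "B") # sqrt(0.3^2 + 0.4^2) = 0.5
#' @export
fit_nma <- function(data, baseline = NULL) {
  data <- validate_contrasts(data)
  treatments <- sort(unique(c(data$treat1, data$treat2)))
  if (is.null(baseline)) baseline <- treatments[1]
  dm <- nma_design_matrix(data, baseline)
  W <- dm$weights
  XtWX <- crossprod(dm$X, dm$X * W)
  XtWy <- crossprod(dm$X, dm$y * W)
  ch <- tryCatch(chol(XtWX), error = function(e) {
    stop("normal equations are singular; the network carries no ",
         "information on some basic comparison", call. = FALSE)
  })
  mu <- drop(backsolve(ch, forwardsolve(t(ch), XtWy)))
  V <- chol2inv(ch)
  basic <- colnames(dm$X)
  names(mu) <- basic
  dimnames(V) <- list(basic, basic)

  # full-parameter view with the baseline pinned at zero
  mu_full <- stats::setNames(numeric(length(treatments)), treatments)
  mu_full[basic] <- mu
  V_full <- matrix(0, length(treatments), length(treatments),
                   dimnames = list(treatments, treatments))
  V_full[basic, basic] <- V

  te <- outer(mu_full, mu_full, "-")
  d <- diag(V_full)
  se <- sqrt(pmax(outer(d, d, "+") - 2 * V_full, 0))

  structure(
    list(
      baseline = baseline,
      treatments = treatments,
      basic_estimates = mu,
      basic_cov = V,
      te_matrix = te,
      se_matrix = se,
      n_studies = length(unique(data$studlab)),
      n_contrasts = nrow(data),
      data = data
    ),
    class = "nma_fit"
  )
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Fixed-effect network meta-analysis\n")
  cat(sprintf("  %d treatments, %d studies, %d contrasts (baseline: %s)\n",
              length(x$treatments), x$n_studies, x$n_contrasts, x$baseline))
  cat("  basic estimates (log odds ratio vs baseline):\n")
  est <- tibble::tibble(
    treatment = names(x$basic_estimates),
    estimate = unname(x$basic_estimates),
    std.error = sqrt(diag(x$basic_cov))
  )
  print(est, ...)
  invisible(x)
}

#' Indirect standard error of a treatment comparison
#'
#' The standard error of the estimated log odds ratio between two
#' treatments implied by the existing network (under consistency). This is
#' the single number the design formulas borrow from the network
#' (`enma_sigma`).
#'
#' @param x An `nma_fit` object or a contrast-level data frame (which is
#'   then fitted).
#' @param treat1,treat2 Treatment labels present in the network.
#' @return The standard error, a single number, invariant to the baseline.
#' @export
indirect_se <- function(x, treat1, treat2) {
  if (!inherits(x, "nma_fit")) x <- fit_nma(x)
  for (tr in c(treat1, treat2)) {
    if (!tr %in% x$treatments) {
      stop(sprintf("treatment '%s' is not in the network", tr),
           call. = FALSE)
    }
  }
  unname(x$se_matrix[treat1, treat2])
}

#' Refit the network with the new trial included
#'
#' Appends the new trial's contrast row to the existing evidence and refits
#' the fixed-effect model, i.e. the updated covariance structure is the
#' existing block plus one independent diagonal entry for the new trial.
#' For the comparison studied by the new trial the updated precision equals
#' the sum of the trial precision and the existing indirect precision.
#'
#' @param data Contrast-level data frame of the existing network.
#' @param new_trial A one-row data frame with columns `studlab`, `treat1`,
#'   `treat2`, `TE`, `seTE`; both treatments must already be in the
#'   network.
#' @param baseline Optional baseline label, as in [fit_nma()].
#' @return An `nma_fit` on the combined evidence.
#' @export
update_network <- function(data, new_trial, baseline = NULL) {
  data <- validate_contrasts(data)
  new_trial <- validate_contrasts(new_trial)
  existing <- unique(c(data$treat1, data$treat2))
  absent <- setdiff(unique(c(new_trial$treat1, new_trial$treat2)), existing)
  if (length(absent) > 0) {
    stop(sprintf("new trial treatment(s) not in the network: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  fit_nma(dplyr::bind_rows(data, new_trial), baseline)
}

# Connectivity of the comparison graph; errors naming the components.
check_connected <- function(data, treatments) {
  g <- igraph::graph_from_data_frame(
    data[, c("treat1", "treat2")], directed = FALSE,
    vertices = data.frame(name = treatments)
  )
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(names(comp$membership), comp$membership)
    stop("network is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = ", "),
               collapse = " | "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of a fitted network
#'
#' One row per ordered treatment pair with the estimated log odds ratio
#' (row treatment relative to column treatment) and its standard error.
#'
#' @param x An `nma_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `treat1`, `treat2`, `estimate`,
#'   `std.error`.
#' @export
tidy.nma_fit <- function(x, ...) {
  tr <- x$treatments
  pairs <- expand.grid(treat2 = tr, treat1 = tr,
                       stringsAsFactors = FALSE)[, c("treat1", "treat2")]
  pairs <- pairs[pairs$treat1 != pairs$treat2, ]
  tibble::tibble(
    treat1 = pairs$treat1,
    treat2 = pairs$treat2,
    estimate = x$te_matrix[cbind(pairs$treat1, pairs$treat2)],
    std.error = x$se_matrix[cbind(pairs$treat1, pairs$treat2)]
  )
}

#' One-row summary of a fitted network
#'
#' @inheritParams tidy.nma_fit
#' @return A tibble with `n_treatments`, `n_studies`, `n_contrasts`,
#'   `baseline`.
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    n_treatments = length(x$treatments),
    n_studies = x$n_studies,
    n_contrasts = x$n_contrasts,
    baseline = x$baseline
  )
}
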