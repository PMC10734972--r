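#' Read contrast-level network meta-analysis data
#'
#' Reads a CSV file with one row per pairwise comparison per study, the
#' standard contrast-level layout with columns `studlab`, `treat1`,
#' `treat2`, `TE` (log odds ratio of `treat1` relative to `treat2`) and
#' `seTE` (its standard error). Extra columns are dropped with a warning.
#' Every row is validated: `TE` finite, `seTE` finite and positive, the two
#' treatment labels distinct after whitespace trimming.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with the five canonical columns, rows in file order.
#' @examples
#' path <- system.file("extdata", "brd_head.csv", package = "nmadesign")
#' read_contrasts(path)
#' @seealso [write_contrasts()], [arms_to_contrasts()], [fit_nma()]
#' @export
read_contrasts <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("studlab", "treat1", "treat2", "TE", "seTE")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(dat), required)
  if (length(extra) > 0) {
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  dat <- dplyr::select(dat, dplyr::all_of(required))
  validate_contrasts(dat)
}

#' Write contrast-level data to CSV
#'
#' Writes the five canonical columns at full precision so that a
#' write/read round trip reproduces `TE` and `seTE` exactly as printed.
#'
#' @param data A contrast-level data frame (see [read_contrasts()]).
#' @param path Output path.
#' @return `data`, invisibly (so the call can sit inside a pipe).
#' @export
write_contrasts <- function(data, path) {
  data <- validate_contrasts(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' Validate contrast-level data
#'
#' Checks the invariants every downstream function relies on and returns
#' the data as a tibble with trimmed treatment labels. Called internally by
#' [read_contrasts()] and [fit_nma()]; exported so user-assembled tibbles
#' can be checked eagerly.
#'
#' @inheritParams write_contrasts
#' @return A validated tibble with columns `studlab`, `treat1`, `treat2`,
#'   `TE`, `seTE`.
#' @export
validate_contrasts <- function(data) {
  required <- c("studlab", "treat1", "treat2", "TE", "seTE")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(data[required])
  out$studlab <- as.character(out$studlab)
  out$treat1 <- trimws(as.character(out$treat1))
  out$treat2 <- trimws(as.character(out$treat2))
  bad_se <- which(!is.finite(out$seTE) | out$seTE <= 0)
  if (length(bad_se) > 0) {
    stop(sprintf("`seTE` must be finite and > 0; offending row(s): %s",
                 paste(bad_se, collapse = ", ")), call. = FALSE)
  }
  bad_te <- which(!is.finite(out$TE))
  if (length(bad_te) > 0) {
    stop(sprintf("`TE` must be finite; offending row(s): %s",
                 paste(bad_te, collapse = ", ")), call. = FALSE)
  }
  bad_tr <- which(out$treat1 == out$treat2)
  if (length(bad_tr) > 0) {
    stop(sprintf("`treat1` and `treat2` must differ; offending row(s): %s",
                 paste(bad_tr, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read arm-level binomial count data
#'
#' Reads a CSV with one row per study arm: `studlab`, `treat`, `r` (event
#' count) and `n` (arm size), validated so that `0 <= r <= n` and `n >= 1`.
#'
#' @inheritParams read_contrasts
#' @return A tibble with the four columns.
#' @seealso [arms_to_contrasts()]
#' @export
read_arms <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_arms(dat)
}

validate_arms <- function(data) {
  required <- c("studlab", "treat", "r", "n")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(data[required])
  out$studlab <- as.character(out$studlab)
  out$treat <- trimws(as.character(out$treat))
  if (any(out$n < 1)) stop("arm size `n` must be >= 1", call. = FALSE)
  if (any(out$r < 0 | out$r > out$n)) {
    stop("event count `r` must satisfy 0 <= r <= n", call. = FALSE)
  }
  out
}

#' Log odds ratio and standard error from two binomial arms
#'
#' The Wald estimator from the 2x2 table:
#' `TE = log((r1/(n1-r1)) / (r2/(n2-r2)))` and
#' `seTE = sqrt(1/r1 + 1/(n1-r1) + 1/r2 + 1/(n2-r2))`, identical to the
#' coefficient and standard error of the corresponding logistic regression.
#' If any of the four cells is zero, 0.5 is added to all four cells of the
#' table before evaluation (Haldane-Anscombe continuity correction).
#'
#' @param r1,n1 Events and size of arm 1 (the `treat1` arm).
#' @param r2,n2 Events and size of arm 2. All vectorised.
#' @return A tibble with columns `TE`, `seTE` and `corrected` (logical,
#'   `TRUE` where the continuity correction was applied).
#' @examples
#' contrast_from_counts(10, 100, 20, 100)
#' @export
contrast_from_counts <- function(r1, n1, r2, n2) {
  if (any(n1 < 1) || any(n2 < 1)) stop("arm sizes must be >= 1", call. = FALSE)
  if (any(r1 < 0 | r1 > n1) || any(r2 < 0 | r2 > n2)) {
    stop("event counts must satisfy 0 <= r <= n", call. = FALSE)
  }
  a <- r1; b <- n1 - r1; c <- r2; d <- n2 - r2
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  tibble::tibble(
    TE = log(a / b) - log(c / d),
    seTE = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
    corrected = corrected
  )
}

#' Convert arm-level data to contrast-level data
#'
#' For every study, forms all pairwise comparisons between its arms (in arm
#' order, so a three-arm study contributes three contrast rows sharing the
#' same `studlab`) and computes the Wald log odds ratio and standard error
#' via [contrast_from_counts()].
#'
#' @param arms Arm-level data frame with columns `studlab`, `treat`, `r`,
#'   `n` (see [read_arms()]).
#' @return A contrast-level tibble as accepted by [fit_nma()].
#' @export
arms_to_contrasts <- function(arms) {
  arms <- validate_arms(arms)
  arms |>
    dplyr::group_by(.data$studlab) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        stop(sprintf("study has a single arm and yields no contrast"),
             call. = FALSE)
      }
      idx <- utils::combn(nrow(df), 2)
      est <- contrast_from_counts(df$r[idx[1, ]], df$n[idx[1, ]],
                                  df$r[idx[2, ]], df$n[idx[2, ]])
      tibble::tibble(
        treat1 = df$treat[idx[1, ]],
        treat2 = df$treat[idx[2, ]],
        TE = est$TE,
        seTE = est$seTE
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("studlab", "treat1", "treat2",
                                  "TE", "seTE")))
}
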