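# Shared fixtures, all built in code.

# A -- C -- B chain with no direct A-B comparison; the indirect A-B
# standard error is sqrt(0.3^2 + 0.4^2) = 0.5.
chain_data <- function() {
  tibble::tibble(
    studlab = c("s1", "s2"),
    treat1 = c("A", "C"),
    treat2 = c("C", "B"),
    TE = c(0.4, 0.2),
    seTE = c(0.3, 0.4)
  )
}

# Small connected network spec used by the simulation tests: the planned
# A-vs-B comparison is informed only through the shared comparator C.
small_spec <- function(arm_size = 200) {
  network_spec(
    risks = c(A = 0.2, B = 0.3, C = 0.5, D = 0.3),
    studies = list(c("A", "C"), c("B", "C"), c("A", "C"), c("B", "C"),
                   c("C", "D"), c("A", "D")),
    arm_size = arm_size
  )
}

# Random non-degenerate sample-size problem: the network alone never
# attains the target, and the continuous required total stays below
# `max_total` so exhaustive verification is cheap.
sample_design_problem <- function(min_lor = 0.35, max_total = 1200) {
  repeat {
    p1 <- stats::runif(1, 0.1, 0.9)
    p2 <- stats::runif(1, 0.1, 0.9)
    lor <- lor_from_risks(p1, p2)
    if (abs(lor) < min_lor) next
    sig <- stats::runif(1, 0.15, 1)
    target <- stats::runif(1, 0.5, 0.9)
    method <- sample(c("with", "without"), 1)
    if (method == "with" && lor_power(lor, sig) >= target * 0.98) next
    v <- nmadesign:::required_sd(lor, target)^2
    prec <- 1 / v - if (method == "with") 1 / sig^2 else 0
    if (prec <= 0) next
    a <- 1 / (p1 * (1 - p1)); b <- 1 / (p2 * (1 - p2))
    if ((sqrt(a) + sqrt(b))^2 / prec > max_total) next
    return(list(p1 = p1, p2 = p2, sig = sig, target = target,
                method = method))
  }
}

# Random connected contrast-level dataset: a spanning tree over the
# treatments plus a few extra edges.
random_network_data <- function(n_treat, n_extra = 2) {
  treats <- LETTERS[seq_len(n_treat)]
  edges <- cbind(treats[-1], treats[pmax(1, seq_len(n_treat - 1))])
  for (i in seq_len(n_extra)) {
    pair <- sample(treats, 2)
    edges <- rbind(edges, pair)
  }
  tibble::tibble(
    studlab = sprintf("s%d", seq_len(nrow(edges))),
    treat1 = unname(edges[, 1]),
    treat2 = unname(edges[, 2]),
    TE = stats::rnorm(nrow(edges)),
    seTE = stats::runif(nrow(edges), 0.1, 0.6)
  )
}
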