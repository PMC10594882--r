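#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test under the hypergeometric null with all margins
#' fixed: the p-value is the sum of the probabilities of every table with the
#' same margins whose probability does not exceed that of the observed table
#' (the probability-mass rule, the common convention for the two-sided exact
#' test).  Degenerate margins (an empty row or column) give p = 1.
#'
#' Implemented directly on the hypergeometric mass function; the test suite
#' cross-checks it against both an exhaustive factorial enumeration oracle
#' and `stats::fisher.test` over all tables with margins up to 12.
#'
#' @param a,b,c,d Cell counts, rows = pipelines, columns = retained /
#'   not retained.  Alternatively pass a 2x2 matrix as `a`.
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(281, 4, 272, 13)
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(!is.na(cells)), all(cells >= 0),
            all(cells == round(cells)))
  if (sum(cells) == 0)
    stop("contingency table has no positive margin")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Binomial confidence intervals
#'
#' Wilson score and Clopper-Pearson (exact) intervals for a binomial
#' proportion.  Wilson is the package default for sensitivity reporting;
#' both are provided because neither method alone reproduces every interval
#' printed in typical reports at two decimal places.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp the degenerate ends exactly (centre - half carries float noise)
  low <- if (x == 0) 0 else max(0, centre - half)
  high <- if (x == n) 1 else min(1, centre + half)
  c(low = low, high = high)
}

#' @rdname wilson_ci
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - conf
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Sensitivity of a pipeline against a gold-positive truth set
#'
#' The fraction of gold-standard pathogenic variant keys retained, with a
#' binomial confidence interval (Wilson score by default, Clopper-Pearson
#' optionally).
#'
#' @param decisions A `g2p_result`, or a decisions data frame with
#'   `variant_key` and `retained`.
#' @param truth Character vector of gold-positive variant keys (non-empty).
#' @param ci_method `"wilson"` or `"clopper_pearson"`.
#' @param conf Confidence level.
#' @return A list of class `g2p_sensitivity` with `retained`, `total`,
#'   `estimate`, `ci_low`, `ci_high`, `ci_method`.
#' @export
sensitivity <- function(decisions, truth, ci_method = c("wilson", "clopper_pearson"),
                        conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(truth) == 0) stop("truth set is empty")
  d <- if (inherits(decisions, "g2p_result")) decisions$decisions else decisions
  retained_keys <- unique(d$variant_key[d$retained])
  x <- sum(truth %in% retained_keys)
  n <- length(unique(truth))
  ci <- switch(ci_method, wilson = wilson_ci(x, n, conf),
               clopper_pearson = clopper_pearson_ci(x, n, conf))
  structure(list(retained = x, total = n, estimate = x / n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 ci_method = ci_method),
            class = "g2p_sensitivity")
}

#' @export
print.g2p_sensitivity <- function(x, ...) {
  cat(sprintf("sensitivity %d/%d = %.3f, %s 95%% CI [%.3f, %.3f]\n",
              x$retained, x$total, x$estimate, x$ci_method, x$ci_low, x$ci_high))
  invisible(x)
}

#' Positive rate of a cohort result
#'
#' The number of unique variant keys retained for downstream review - the
#' analytical burden a pipeline leaves for manual interpretation.
#'
#' @param result A `g2p_result`.
#' @return Integer count.
#' @export
positive_rate <- function(result) {
  stopifnot(inherits(result, "g2p_result"))
  result$unique_variants_retained
}

#' Compare pipelines: retained counts, sensitivities, pairwise Fisher tests
#'
#' Builds the per-pipeline summary (unique variants considered/retained,
#' sensitivity with confidence interval when a truth set is supplied) and all
#' pairwise two-sided Fisher exact tests.  With a truth set the 2x2 tables
#' compare gold positives retained vs missed; without one they compare
#' retained vs not-retained out of the variants considered (positive-rate
#' comparison).
#'
#' @param results Named list of `g2p_result`, one per pipeline (>= 2).
#' @param truth Optional character vector of gold-positive variant keys.
#' @param ci_method Passed to [sensitivity()].
#' @return A list of class `g2p_comparison` with data frames `per_pipeline`
#'   and `pairwise`.
#' @export
compare_pipelines <- function(results, truth = NULL,
                              ci_method = c("wilson", "clopper_pearson")) {
  ci_method <- match.arg(ci_method)
  if (length(results) < 2) stop("need results for at least 2 pipelines")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("pipeline", seq_along(results))
  per <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    row <- data.frame(pipeline = nm,
                      considered = r$unique_variants_considered,
                      retained = r$unique_variants_retained,
                      stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      s <- sensitivity(r, truth, ci_method)
      row$sensitivity <- s$estimate
      row$ci_low <- s$ci_low; row$ci_high <- s$ci_high
    }
    row
  }))
  nm <- names(results)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    if (!is.null(truth)) {
      x1 <- sensitivity(results[[p[1]]], truth, ci_method)
      x2 <- sensitivity(results[[p[2]]], truth, ci_method)
      tab <- c(x1$retained, x1$total - x1$retained,
               x2$retained, x2$total - x2$retained)
    } else {
      r1 <- results[[p[1]]]; r2 <- results[[p[2]]]
      tab <- c(r1$unique_variants_retained,
               r1$unique_variants_considered - r1$unique_variants_retained,
               r2$unique_variants_retained,
               r2$unique_variants_considered - r2$unique_variants_retained)
    }
    data.frame(pipeline_a = p[1], pipeline_b = p[2],
               a = tab[1], b = tab[2], c = tab[3], d = tab[4],
               p_fisher = fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_pipeline = per, pairwise = pairwise),
            class = "g2p_comparison")
}

#' @export
print.g2p_comparison <- function(x, ...) {
  print(x$per_pipeline, row.names = FALSE)
  cat("\npairwise Fisher (two-sided, p to 2 s.f.):\n")
  pw <- x$pairwise
  pw$p_fisher <- signif(pw$p_fisher, 2)
  print(pw, row.names = FALSE)
  invisible(x)
}
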