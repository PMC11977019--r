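#' Friedman rank test across k paired models
#'
#' Nonparametric within-subject comparison of `k >= 3` models measured on
#' the same `n` subjects (e.g. one metric per video). Values are ranked
#' within each subject (average ranks on ties) and the classical statistic
#' `chi2 = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)` is referred to a
#' chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param values Numeric `n x k` matrix (subjects x models) or a data
#'   frame coercible to one; column names are the model ids.
#' @return A `cw_test` with fields `statistic` (chi-squared), `p_value`,
#'   `n`, `dof`.
#' @examples
#' m <- rbind(c(0.9, 0.7, 0.5), c(0.8, 0.6, 0.4))
#' friedman_test(m)  # identical rankings: chi2 = 4
#' @export
friedman_test <- function(values) {
  m <- as.matrix(values)
  n <- nrow(m); k <- ncol(m)
  if (k < 3) {
    abort("friedman_test needs k >= 3 models; use wilcoxon_signed_rank for a pair")
  }
  if (n < 2) abort("friedman_test needs n >= 2 subjects")
  if (anyNA(m)) abort("friedman_test: missing values (drop subjects first)")
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  new_cw_test(method = "Friedman rank test", statistic = chi2,
              statistic_name = "chi_squared",
              p_value = pchisq(chi2, df = k - 1, lower.tail = FALSE),
              n = n, dof = k - 1L)
}

#' Wilcoxon signed-rank test for a pair of models
#'
#' Paired two-sided test of `a` against `b`. Zero differences are dropped;
#' absolute differences are ranked with average ranks on ties; the
#' statistic is `T+`, the rank sum of positive differences of `a - b`
#' (`T+ = 0` means the first model never exceeded the second). The p-value
#' is exact — computed from the full distribution of `T+` over all `2^n`
#' sign patterns, respecting the observed tie structure — for `n <= 25`,
#' and a normal approximation with tie and continuity corrections beyond
#' that.
#'
#' @param a,b Equal-length numeric vectors, paired by subject.
#' @return A `cw_test` with fields `statistic` (`T+`), `p_value`, `n`
#'   (pairs after dropping zero differences), `exact`.
#' @examples
#' wilcoxon_signed_rank(2:11, 1:10)  # T+ = 55, p = 2/1024
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("all differences are zero; degenerate test")
    return(new_cw_test(method = "Wilcoxon signed-rank test", statistic = 0,
                       statistic_name = "T_plus", p_value = 1, n = 0L,
                       exact = TRUE))
  }
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  exact <- n <= 25L
  if (exact) {
    # distribution of 2*T+ by dynamic programming over the rank multiset
    s <- as.integer(round(2 * r))
    dp <- numeric(sum(s) + 1L); dp[1L] <- 1
    for (si in s) {
      shifted <- c(numeric(si), dp[seq_len(length(dp) - si)])
      dp <- dp + shifted
    }
    total <- 2^n
    t2 <- as.integer(round(2 * t_plus))
    p_le <- sum(dp[seq_len(t2 + 1L)]) / total
    p_ge <- sum(dp[(t2 + 1L):length(dp)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (t_plus - mu - sign(t_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  new_cw_test(method = "Wilcoxon signed-rank test", statistic = t_plus,
              statistic_name = "T_plus", p_value = p, n = n, exact = exact)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p-values:
#' `adjusted_(i) = min over j >= i of m * p_(j) / j`, capped at 1.
#' Adjusted values are never below the raw values and the procedure is
#' idempotent.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

new_cw_test <- function(method, statistic, statistic_name, p_value, n,
                        dof = NA_integer_, exact = NA) {
  structure(list(method = method, statistic = statistic,
                 statistic_name = statistic_name, p_value = p_value,
                 n = n, dof = dof, exact = exact),
            class = "cw_test")
}

#' @export
print.cw_test <- function(x, ...) {
  cat(sprintf("%s: %s = %g, p = %.4g (n = %d%s)\n", x$method,
              x$statistic_name, x$statistic, x$p_value, x$n,
              if (!is.na(x$dof)) sprintf(", dof = %d", x$dof) else ""))
  invisible(x)
}

#' Tidy a cagewatch test result
#'
#' @param x A `cw_test`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic_name`, `statistic`,
#'   `p_value`, `n`, `dof`.
#' @export
tidy.cw_test <- function(x, ...) {
  tibble(method = x$method, statistic_name = x$statistic_name,
         statistic = x$statistic, p_value = x$p_value,
         n = x$n, dof = x$dof)
}

#' @rdname tidy.cw_test
#' @export
glance.cw_test <- function(x, ...) tidy(x, ...)

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Nonparametric comparison of detection models
#'
#' Given one or more performance metrics measured for `k` models on the
#' same subjects (videos or individuals), runs the Friedman test across
#' all models (when `k >= 3`) and Wilcoxon signed-rank tests for every
#' model pair, per metric, with Benjamini-Hochberg correction applied
#' within each metric's family of pairwise comparisons. Subjects with an
#' undefined metric under any model are dropped listwise for that metric
#' (with a warning).
#'
#' @param data Long tibble with columns `subject`, `model`, and one column
#'   per metric named in `metrics`.
#' @param metrics Character vector of metric column names (default
#'   `c("precision", "recall", "f1")`, intersected with what is present).
#' @return A tibble with one row per test: `metric`, `test`, `comparison`,
#'   `n`, `dof`, `statistic_name`, `statistic`, `p_value`, `p_adjusted`
#'   (NA for Friedman rows; pairwise rows corrected within metric).
#' @export
compare_models <- function(data, metrics = c("precision", "recall", "f1")) {
  data <- as_tibble(data)
  stopifnot(all(c("subject", "model") %in% names(data)))
  metrics <- intersect(metrics, names(data))
  if (!length(metrics)) abort("compare_models: no metric columns found")
  models <- unique(data$model)
  k <- length(models)
  if (k < 2) abort("compare_models needs at least 2 models")

  purrr::map_dfr(metrics, function(mc) {
    wide <- tidyr::pivot_wider(data[c("subject", "model", mc)],
                               names_from = "model",
                               values_from = dplyr::all_of(mc))
    m <- as.matrix(wide[models])
    keep <- stats::complete.cases(m)
    if (any(!keep)) {
      warn(sprintf("%s: dropping %d subject(s) with undefined values",
                   mc, sum(!keep)))
    }
    m <- m[keep, , drop = FALSE]

    rows <- list()
    if (k >= 3) {
      fr <- friedman_test(m)
      rows[[1]] <- tibble(metric = mc, test = "friedman",
                          comparison = paste(models, collapse = " vs "),
                          n = fr$n, dof = fr$dof,
                          statistic_name = "chi_squared",
                          statistic = fr$statistic, p_value = fr$p_value,
                          p_adjusted = NA_real_)
    }
    pairs <- utils::combn(models, 2, simplify = FALSE)
    pw <- purrr::map_dfr(pairs, function(pr) {
      wt <- wilcoxon_signed_rank(m[, pr[1]], m[, pr[2]])
      tibble(metric = mc, test = "wilcoxon",
             comparison = paste(pr, collapse = " vs "),
             n = wt$n, dof = NA_integer_, statistic_name = "T_plus",
             statistic = wt$statistic, p_value = wt$p_value,
             p_adjusted = NA_real_)
    })
    pw$p_adjusted <- benjamini_hochberg(pw$p_value)
    dplyr::bind_rows(c(rows, list(pw)))
  })
}
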