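#' Spearman rank correlation with a confidence interval
#'
#' The coefficient is the product-moment correlation of mid-ranks (ties
#' receive average ranks). The confidence interval uses either the Fisher
#' z-transform with variance 1/(n-3) (default) or a percentile bootstrap
#' over resampled pairs; the p-value comes from the large-sample t
#' approximation with n - 2 degrees of freedom. Rank correlation is the
#' appropriate choice for small cohorts with non-normal feature
#' distributions.
#'
#' @param x,y Numeric vectors of equal length (n >= 4); ties allowed.
#' @param ci_method `"fisher-z"` or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `pw_correlation` with fields `rho`, `ci_low`,
#'   `ci_high`, `n`, `p_value`, `ci_method`; [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @examples
#' spearman_with_ci(1:10, (1:10)^2)
#' @export
spearman_with_ci <- function(x, y, ci_method = c("fisher-z", "bootstrap"),
                             conf_level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal lengths.",
          class = "pk_invalid_input")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) {
    abort("need at least 4 complete pairs.", class = "pk_invalid_input")
  }
  if (sd(x) < 1e-300 || sd(y) < 1e-300) {
    abort("correlation undefined for constant input.",
          class = "pk_undefined_correlation")
  }
  rho <- cor(rank(x), rank(y))
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "fisher-z") {
    fz <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
    half <- z / sqrt(n - 3)
    ci <- tanh(c(fz - half, fz + half))
  } else {
    boot <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (sd(x[i]) < 1e-300 || sd(y[i]) < 1e-300) return(NA_real_)
        cor(rank(x[i]), rank(y[i]))
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), na.rm = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(rho = rho, ci_low = min(ci[1], rho), ci_high = max(ci[2], rho),
                 n = n, p_value = min(p, 1), ci_method = ci_method,
                 conf_level = conf_level, data = tibble(x = x, y = y)),
            class = "pw_correlation")
}

#' @export
print.pw_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f  (%d%% CI %.4f to %.4f, %s), n = %d, p = %.4g\n",
              x$rho, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n, x$p_value))
  invisible(x)
}

#' Assign the coronary-disease stage group
#'
#' Four stages by angiographic findings: group 1, normal coronaries
#' (no stenosis); group 2, minimal/moderate narrowing (at most 50%
#' diameter decrease); group 3, medium lesions (51-75%) that are not
#' revascularization targets and involve at most two vessels; group 4,
#' significant disease (51-100%) that is a revascularization target or
#' three-vessel disease. Lesions above 75% that are explicitly not flagged
#' for revascularization fall outside the published partition, so they
#' raise a classification-ambiguity error rather than being silently
#' binned.
#'
#' @param record A [patient_record()] row or a data frame with columns
#'   `stenosis_max`, `revascularization_object`, `three_vessel`.
#' @return Integer vector of group labels 1-4.
#' @export
assign_cad_group <- function(record) {
  sten <- record$stenosis_max
  rev <- record$revascularization_object
  tv <- record$three_vessel
  if (any(is.na(sten))) {
    abort("`stenosis_max` must be defined.", class = "pk_missing_data")
  }
  out <- integer(length(sten))
  for (i in seq_along(sten)) {
    out[i] <- if (sten[i] == 0) {
      1L
    } else if (sten[i] <= 50) {
      2L
    } else if (rev[i] || tv[i]) {
      4L
    } else if (sten[i] <= 75) {
      3L
    } else {
      abort(sprintf(
        "patient %s: stenosis %.0f%% above 75%% with neither revascularization nor three-vessel flag is not classifiable.",
        if ("patient_id" %in% names(record)) record$patient_id[i] else i,
        sten[i]), class = "pk_ambiguous_group")
    }
  }
  out
}

RISK_FLAGS <- c("hypertension", "dyslipidemia_untreated", "bmi_over_35",
                "smoking", "diabetes", "vascular_pathology")

#' Count cardiovascular risk factors
#'
#' Sums the six tracked flags: hypertension, untreated dyslipidemia,
#' BMI > 35, current/former smoking, diabetes mellitus, and arterial
#' vascular disease outside the coronaries.
#'
#' @param record A [patient_record()] row or data frame with the six
#'   logical flag columns.
#' @return Integer vector of counts 0-6.
#' @export
count_risk_factors <- function(record) {
  miss <- setdiff(RISK_FLAGS, names(record))
  if (length(miss)) {
    abort(sprintf("missing risk flag(s): %s.", paste(miss, collapse = ", ")),
          class = "pk_missing_data")
  }
  flags <- as.matrix(as.data.frame(record)[, RISK_FLAGS])
  if (any(is.na(flags))) {
    abort("risk flags must not be missing.", class = "pk_missing_data")
  }
  as.integer(rowSums(flags))
}

# cache of combination index matrices for exact rank-sum enumeration
.combn_cache <- new.env(parent = emptyenv())

exact_ranksum_p <- function(v1, v2) {
  n1 <- length(v1); n <- n1 + length(v2)
  r <- rank(c(v1, v2))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  key <- paste(n, n1, sep = "_")
  if (!exists(key, envir = .combn_cache)) {
    assign(key, utils::combn(n, n1), envir = .combn_cache)
  }
  cmb <- get(key, envir = .combn_cache)
  wall <- colSums(matrix(r[cmb], nrow = n1))
  mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
}

#' Compare a metric between patient groups
#'
#' Per-group medians with quartiles, and a two-sided rank-sum test either
#' comparing group 1 against all other groups pooled (`"1-vs-rest"`) or
#' every pair of groups (`"all-pairs"`). The p-value is computed by exact
#' enumeration of all group-label assignments whenever the smaller group
#' has at most 8 members and the enumeration stays tractable (at most
#' 5e6 combinations), and by the tie-corrected normal approximation
#' otherwise. Exact enumeration handles ties correctly, which the standard
#' exact distribution does not.
#'
#' @param values Numeric per-patient metric.
#' @param groups Group labels (coercible to factor), same length.
#' @param split `"1-vs-rest"` (first group level against the rest) or
#'   `"all-pairs"`.
#' @param max_enum Enumeration budget for the exact test.
#' @return An object of class `pw_group_comparison` with `summary`
#'   (group, n, median, q1, q3) and `tests` (comparison, p_value, method)
#'   tibbles; `tidy()`/`glance()` methods are provided.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2))
#' @export
compare_groups <- function(values, groups,
                           split = c("1-vs-rest", "all-pairs"),
                           max_enum = 5e6) {
  split <- match.arg(split)
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal lengths.",
          class = "pk_invalid_input")
  }
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  tab <- table(groups)
  if (any(tab == 0)) {
    warn("dropping empty group level(s).")
    groups <- droplevels(groups)
    tab <- table(groups)
  }
  if (length(tab) < 2) {
    abort("need at least two non-empty groups.",
          class = "pk_invalid_input")
  }
  summary <- tibble(
    group = names(tab),
    n = as.integer(tab),
    median = as.numeric(tapply(values, groups, median)),
    q1 = as.numeric(tapply(values, groups, quantile, probs = 0.25)),
    q3 = as.numeric(tapply(values, groups, quantile, probs = 0.75))
  )
  one_test <- function(v1, v2, label) {
    n1 <- length(v1); n2 <- length(v2)
    exact <- min(n1, n2) <= 8 &&
      choose(n1 + n2, min(n1, n2)) <= max_enum
    if (exact) {
      p <- if (n1 <= n2) exact_ranksum_p(v1, v2) else exact_ranksum_p(v2, v1)
      method <- "exact rank-sum (enumeration)"
    } else {
      p <- stats::wilcox.test(v1, v2, exact = FALSE, correct = TRUE)$p.value
      method <- "rank-sum (normal approximation)"
    }
    tibble(comparison = label, p_value = p, method = method)
  }
  lev <- levels(groups)
  tests <- if (split == "1-vs-rest") {
    one_test(values[groups == lev[1]], values[groups != lev[1]],
             sprintf("%s vs rest", lev[1]))
  } else {
    purrr::map_dfr(utils::combn(lev, 2, simplify = FALSE), function(pr) {
      one_test(values[groups == pr[1]], values[groups == pr[2]],
               paste(pr, collapse = " vs "))
    })
  }
  structure(list(summary = summary, tests = tests, split = split,
                 data = tibble(value = values, group = groups)),
            class = "pw_group_comparison")
}

#' @export
print.pw_group_comparison <- function(x, ...) {
  cat("Group summary:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("Tests:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}
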