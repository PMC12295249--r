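#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Spearman correlation result
#'
#' @param x A `pw_correlation` from [spearman_with_ci()].
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, `method`.
#' @export
tidy.pw_correlation <- function(x, ...) {
  tibble(estimate = x$rho, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_value, n = x$n,
         method = paste0("spearman/", x$ci_method))
}

#' @rdname tidy.pw_correlation
#' @export
glance.pw_correlation <- function(x, ...) tidy(x, ...)

#' Tidy a group comparison
#'
#' `tidy()` returns the per-group summary joined with nothing else;
#' `glance()` returns the test rows.
#'
#' @param x A `pw_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @export
tidy.pw_group_comparison <- function(x, ...) x$summary

#' @rdname tidy.pw_group_comparison
#' @export
glance.pw_group_comparison <- function(x, ...) x$tests
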