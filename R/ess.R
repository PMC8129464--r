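#' Beta moment matching and prior effective sample size
#'
#' Approximates a marginal predictive distribution for a DLT risk by the
#' Beta(a, b) distribution with the same first two moments.  The
#' effective sample size (ESS) of the approximated prior is `a + b`: the
#' number of hypothetical patients the prior is worth.  Closed form:
#' \deqn{\mathrm{ess} = m(1-m)/s^2 - 1,\quad a = m\cdot\mathrm{ess},\quad
#'   b = (1-m)\cdot\mathrm{ess}.}
#'
#' A variance at or above `m(1-m)` admits no Beta distribution; such
#' inputs raise an error rather than being clamped, since a silently
#' clamped ESS would corrupt comparisons across doses.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation, `0 < sd^2 < mean * (1 - mean)`.
#' @return An object of class `beta_approx`: list with `a`, `b`, `ess`.
#' @examples
#' beta_moment_match(0.027, 0.031)  # ess ~ 26.3
#' @export
beta_moment_match <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)")
  if (sd <= 0) stop("sd must be positive")
  if (sd^2 >= mean * (1 - mean))
    stop("sd^2 >= mean*(1-mean): no Beta distribution has these moments")
  ess <- mean * (1 - mean) / sd^2 - 1
  structure(list(a = mean * ess, b = (1 - mean) * ess, ess = ess),
            class = "beta_approx")
}

#' @export
print.beta_approx <- function(x, ...) {
  cat(sprintf("Beta(a = %.3f, b = %.3f), ESS = %.3f\n", x$a, x$b, x$ess))
  invisible(x)
}

#' Effective sample sizes for a table of predictive summaries
#'
#' Vectorised [beta_moment_match()] over the rows of a per-dose summary
#' table (as produced by [summarize_risk()]), preserving dose order.  A
#' row violating the moment-matching preconditions raises an error
#' identifying the offending dose.
#'
#' @param summaries A data.frame with columns `mean` and `sd` (and
#'   optionally `dose`, carried through).
#' @return The input with columns `ess`, `a`, `b` appended.
#' @export
ess_table <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c("mean", "sd") %in% names(summaries)))
  out <- summaries
  out$ess <- out$a <- out$b <- NA_real_
  for (i in seq_len(nrow(summaries))) {
    fit <- tryCatch(beta_moment_match(summaries$mean[i], summaries$sd[i]),
                    error = function(e) {
                      lbl <- if ("dose" %in% names(summaries))
                        paste0("dose ", summaries$dose[i]) else paste0("row ", i)
                      stop(lbl, ": ", conditionMessage(e), call. = FALSE)
                    })
    out$ess[i] <- fit$ess; out$a[i] <- fit$a; out$b[i] <- fit$b
  }
  out
}
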