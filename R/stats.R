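# Summary statistics and two-sample comparisons from summary data, matching
# the mean +/- SEM reporting convention of bilayer conductance work.

#' Summarize a sample as mean, SEM and n
#'
#' @param values numeric vector with at least two values.
#' @return object of class `sample_summary`: `mean`, `sem` (sd/sqrt(n), sd
#'   with the n-1 denominator), `n`.
#' @export
#' @examples
#' summarize_sample(c(0, 2))  # mean 1, sem 1
summarize_sample <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values to summarize")
  sample_summary(mean(values), stats::sd(values) / sqrt(n), n)
}

#' Construct a sample summary from published mean +/- SEM
#'
#' @param mean sample mean.
#' @param sem standard error of the mean (non-negative).
#' @param n sample size (>= 2).
#' @return object of class `sample_summary`.
#' @export
sample_summary <- function(mean, sem, n) {
  if (n < 2) stop("n must be at least 2")
  if (sem < 0) stop("sem must be non-negative")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

.as_summary <- function(x) {
  if (inherits(x, "sample_summary")) return(x)
  if (is.numeric(x) && length(x) > 1) return(summarize_sample(x))
  if (is.list(x)) return(sample_summary(x$mean, x$sem, x$n))
  stop("cannot interpret object as a sample summary")
}

#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test computed from (mean, SEM, n) triplets:
#' t = (mean_a - mean_b) / sqrt(sem_a^2 + sem_b^2) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. The pooled-variance Student
#' form is available via `pooled = TRUE`. With both SEMs zero the test is
#' degenerate: equal means give t = 0, p = 1; unequal means give p = 0 with
#' a `degenerate` flag.
#'
#' @param a,b `sample_summary` objects (or raw numeric vectors, summarized
#'   on the fly, or lists with `mean`, `sem`, `n`).
#' @param pooled use the pooled-variance Student's t instead of Welch.
#' @return object of class `t_test_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `method`, `degenerate`.
#' @export
#' @examples
#' welch_t(sample_summary(10.34, 1.65, 310), sample_summary(10.45, 5.06, 37))
welch_t <- function(a, b, pooled = FALSE) {
  a <- .as_summary(a)
  b <- .as_summary(b)
  dm <- a$mean - b$mean
  degenerate <- FALSE
  if (a$sem == 0 && b$sem == 0) {
    degenerate <- dm != 0
    t <- if (dm == 0) 0 else sign(dm) * Inf
    df <- a$n + b$n - 2
    p <- if (dm == 0) 1 else 0
  } else if (pooled) {
    va <- (a$sem^2) * a$n  # per-observation variance
    vb <- (b$sem^2) * b$n
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    t <- dm / se
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    se2 <- a$sem^2 + b$sem^2
    t <- dm / sqrt(se2)
    df <- se2^2 / (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 method = if (pooled) "pooled Student" else "Welch",
                 degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> %s t = %.4g, df = %.2f, p = %.4g%s\n",
              x$method, x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$degenerate) " (degenerate: zero SEMs, unequal means)"
              else ""))
  invisible(x)
}
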