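#' Shortest interval containing a given posterior mass
#'
#' Computes the highest posterior density (HPD) interval from a vector of
#' posterior samples as the shortest contiguous window of the sorted draws
#' containing `prob` of them.
#'
#' @param x numeric vector of posterior samples.
#' @param prob posterior mass to cover (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for an HPD interval")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Posterior summary: median, HPD95% and sign probability
#'
#' Summarises a vector of posterior samples the way variance components and
#' genetic correlations are reported: posterior median, the shortest interval
#' containing 95% of the samples, and `P0`, the posterior probability that the
#' parameter shares the sign of its median (the larger of the fractions of
#' draws above and below zero).
#'
#' @param x numeric vector of posterior samples (>= `min_n` required).
#' @param prob mass of the HPD interval.
#' @param min_n minimum number of samples accepted (default 100).
#' @return object of class `posterior_summary`: list with `median`, `hpd`
#'   (length-2), `p0`, `mean`, `sd`, `n`.
#' @export
posterior_summary <- function(x, prob = 0.95, min_n = 100) {
  x <- as.numeric(x)
  if (length(x) < min_n)
    stop("too few samples (", length(x), "); need >= ", min_n)
  med <- stats::median(x)
  p_pos <- mean(x > 0)
  p_neg <- mean(x < 0)
  out <- list(
    median = med,
    hpd = hpd_interval(x, prob),
    p0 = max(p_pos, p_neg),
    mean = mean(x),
    sd = stats::sd(x),
    n = length(x)
  )
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("median %.4f  HPD95%% [%.4f, %.4f]  P0 %.3f  (n = %d)\n",
              x$median, x$hpd[1], x$hpd[2], x$p0, x$n))
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Deterministic 32-bit-safe seed derived from a master seed and a text
#' label, so that per-trait or per-pair fits get independent streams whose
#' results do not depend on execution order.
#'
#' @param seed master integer seed.
#' @param label any string (e.g. a trait-pair name).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_symmetric <- function(m, tol = 1e-8, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(name, " must be square")
  if (max(abs(m - t(m))) > tol) stop(name, " is not symmetric")
  invisible(TRUE)
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}
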