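#' Estimate the TRBC1 positivity threshold from a reference population
#'
#' Fits a two-component univariate Gaussian mixture (EM) to transformed
#' TRBC1 intensities of a polyclonal CD3+ TCRgd- reference and returns the
#' equal-posterior decision boundary between the two component means. This
#' automates the visual threshold an operator would place between the
#' TRBC1-negative and TRBC1-positive benign T-cell modes.
#'
#' @param reference_trbc1 numeric vector of transformed TRBC1 intensities,
#'   at least 500 events.
#' @param max_iter,tol EM iteration controls.
#' @return Scalar threshold on the transformed scale, strictly between the
#'   two component means.
#' @export
#' @examples
#' x <- c(rnorm(600, 1, 0.3), rnorm(400, 3, 0.3))
#' estimate_trbc1_threshold(x)
estimate_trbc1_threshold <- function(reference_trbc1, max_iter = 200, tol = 1e-8) {
  x <- reference_trbc1[is.finite(reference_trbc1)]
  if (length(x) < 500) {
    stop("need at least 500 reference events to estimate a TRBC1 threshold",
         call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(q[1], q[2])
  sig <- rep(max(sd(x) / 2, 1e-3), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sig[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi1 <- mean(g)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sig[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    sig[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    sig <- pmax(sig, 1e-4)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sig <- rev(sig); pi1 <- 1 - pi1
  }
  pooled_sd <- sqrt(pi1 * sig[1]^2 + (1 - pi1) * sig[2]^2)
  if (abs(mu[2] - mu[1]) < pooled_sd) {
    stop("reference TRBC1 distribution looks unimodal; supply a manual ",
         "threshold via the configuration", call. = FALSE)
  }
  .posterior_boundary(mu, sig, c(pi1, 1 - pi1))
}

# equal-posterior point between the two means: solve
# pi1 N(x; mu1, s1) = pi2 N(x; mu2, s2) on (mu1, mu2)
.posterior_boundary <- function(mu, sig, w) {
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sig[2], log = TRUE)
  }
  lo <- mu[1] + 1e-9
  hi <- mu[2] - 1e-9
  if (f(lo) <= 0 || f(hi) >= 0) return((mu[1] + mu[2]) / 2)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' TRBC1 clonality call for one event mask
#'
#' The fraction of events above the TRBC1 threshold decides the verdict:
#' monotypic iff the fraction is strictly below `lower_bound` (0.15) or
#' strictly above `upper_bound` (0.85); populations with fewer than
#' `min_events` (50) events are never assessed.
#'
#' @param events transformed [event_table()].
#' @param mask logical event mask of the population.
#' @param threshold TRBC1 positivity threshold on the transformed scale.
#' @param params `clonality` block of [default_config()].
#' @return list with `n_events`, `trbc1_fraction` and
#'   `verdict` (`"monotypic"`, `"polytypic"` or `"not_assessed"`).
#' @export
call_clonality <- function(events, mask, threshold,
                           params = default_config()$clonality) {
  stopifnot(inherits(events, "event_table"), events$transformed)
  n <- sum(mask)
  if (n == 0) {
    return(list(n_events = 0L, trbc1_fraction = NA_real_,
                verdict = "not_assessed"))
  }
  frac <- sum(chan(events, "TRBC1")[mask] > threshold) / n
  verdict <- if (n < params$min_events) {
    "not_assessed"
  } else if (frac < params$lower_bound || frac > params$upper_bound) {
    "monotypic"
  } else {
    "polytypic"
  }
  list(n_events = as.integer(n), trbc1_fraction = frac, verdict = verdict)
}

#' Population size as percent of CD45+ and of CD3+ events
#'
#' @param n_events population event count.
#' @param cd45_total,cd3_total denominators; must be positive.
#' @return list with `pct_cd45` and `pct_cd3` (percent).
#' @export
population_size <- function(n_events, cd45_total, cd3_total) {
  if (cd45_total <= 0 || cd3_total <= 0) {
    stop("population size denominators must be positive", call. = FALSE)
  }
  list(pct_cd45 = 100 * n_events / cd45_total,
       pct_cd3 = 100 * n_events / cd3_total)
}

#' Per-marker median fluorescence intensity
#'
#' @param events [event_table()]; MFIs are conventionally reported on the
#'   raw intensity scale, so pass raw events (transformed-scale medians used
#'   internally are computed the same way on transformed events).
#' @param mask non-empty logical event mask.
#' @param markers marker names; defaults to the seven antigens recorded for
#'   every population.
#' @return named numeric vector of medians.
#' @export
compute_mfi <- function(events, mask,
                        markers = c("CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD45")) {
  stopifnot(inherits(events, "event_table"))
  if (!any(mask)) stop("cannot compute MFI on an empty mask", call. = FALSE)
  apply(events$exprs[mask, markers, drop = FALSE], 2, median)
}
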