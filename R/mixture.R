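# Gaussian mixture modelling of log10 retraction distances.
#
# Retraction distances are log-normal; at intermediate maturity the
# log10 distribution turns biphasic (short and long retractors). The fit
# compares 1- and 2-component normal mixtures on log10 values by BIC and
# reports the posterior-equality boundary separating the components.

#' Fit 1- and 2-component normal mixtures to log10 retraction distances
#'
#' Expectation-maximization fits on the log10 scale. The two-component
#' fit is restarted from several quantile-seeded initializations (the
#' component means start at a spread of sample-quantile pairs) and the
#' best log-likelihood wins. BIC (-2 logLik + npar log n) selects between
#' k = 1 and k = 2; for k = 2 the boundary where the two components'
#' posterior responsibilities are equal is also returned, in um.
#'
#' @param log10_distances Finite log10 retraction distances (n >= 10).
#' @param k_max Largest number of components (1 or 2).
#' @param restarts Number of EM initializations for k = 2.
#' @param seed Integer seed (jitters the quantile seeds).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sd_floor Lower bound on component standard deviations.
#'
#' @return An object of class `mixture_fit`: a list with per-k fits
#'   (`weights`, `means`, `sds`, `loglik`, `bic`), the selected `k`,
#'   and `boundary_um` (`NA` for k = 1).
#' @export
#' @examples
#' x <- c(rnorm(150, 1.5, 0.15), rnorm(150, 2.2, 0.15))
#' fit_retraction_mixture(x, seed = 3)
fit_retraction_mixture <- function(log10_distances, k_max = 2,
                                   restarts = 10, seed = 1,
                                   max_iter = 500, tol = 1e-8,
                                   sd_floor = 1e-3) {
  x <- log10_distances
  if (any(!is.finite(x))) abort("log10 distances must be finite")
  n <- length(x)
  if (n < 10) abort("need at least 10 values")
  k_max <- match.arg(as.character(k_max), c("1", "2"))
  k_max <- as.integer(k_max)

  fit1 <- list(k = 1L, weights = 1, means = mean(x),
               sds = max(sqrt(mean((x - mean(x))^2)), sd_floor))
  fit1$loglik <- sum(dnorm(x, fit1$means, fit1$sds, log = TRUE))
  fit1$bic <- -2 * fit1$loglik + 2 * log(n)

  degenerate <- sd(x) == 0
  if (degenerate) {
    warn("all values identical: returning a single component at the sd floor")
  }

  fits <- list(`1` = fit1)
  if (k_max == 2 && !degenerate) {
    probs <- list(c(0.25, 0.75), c(0.1, 0.9), c(0.35, 0.65), c(0.15, 0.85),
                  c(0.05, 0.95), c(0.3, 0.7), c(0.2, 0.8), c(0.4, 0.6),
                  c(0.45, 0.55), c(0.1, 0.5))
    best <- NULL
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        pr <- probs[[(r - 1) %% length(probs) + 1]]
        mu0 <- as.numeric(quantile(x, pr)) + rnorm(2, 0, 0.01 * sd(x))
        f <- em_normal2(x, mu0, sd0 = rep(sd(x) / 2, 2), w0 = c(0.5, 0.5),
                        max_iter = max_iter, tol = tol,
                        sd_floor = sd_floor)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
    })
    best$k <- 2L
    best$bic <- -2 * best$loglik + 5 * log(n)
    # order components by mean
    o <- order(best$means)
    best$means <- best$means[o]
    best$sds <- best$sds[o]
    best$weights <- best$weights[o]
    fits$`2` <- best
  }

  k_sel <- if (length(fits) == 2 && fits$`2`$bic < fits$`1`$bic) 2L else 1L
  boundary <- NA_real_
  if (k_sel == 2L) {
    boundary <- posterior_boundary(fits$`2`)
  }
  structure(list(fits = fits, k = k_sel,
                 weights = fits[[as.character(k_sel)]]$weights,
                 means = fits[[as.character(k_sel)]]$means,
                 sds = fits[[as.character(k_sel)]]$sds,
                 loglik = fits[[as.character(k_sel)]]$loglik,
                 bic = vapply(fits, function(f) f$bic, numeric(1)),
                 boundary_um = boundary, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d selected by BIC (%s)\n", x$k,
              paste(sprintf("k=%s: %.1f", names(x$bic), x$bic),
                    collapse = ", ")))
  for (i in seq_along(x$means)) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f (log10 um)\n",
                i, x$weights[i], x$means[i], x$sds[i]))
  }
  if (x$k == 2) {
    cat(sprintf("  posterior-equality boundary: %.1f um\n", x$boundary_um))
  }
  invisible(x)
}

em_normal2 <- function(x, mu0, sd0, w0, max_iter, tol, sd_floor) {
  mu <- mu0
  s <- pmax(sd0, sd_floor)
  w <- w0
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(g)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # a component died
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    s <- c(sqrt(sum(g * (x - mu[1])^2) / n1),
           sqrt(sum((1 - g) * (x - mu[2])^2) / n2))
    s <- pmax(s, sd_floor)
    w <- c(n1 / n, n2 / n)
  }
  list(weights = w, means = mu, sds = s, loglik = ll_old)
}

# Point between the component means where posterior responsibilities are
# equal: solve w1 N(x; m1, s1) = w2 N(x; m2, s2).
posterior_boundary <- function(fit) {
  m <- fit$means; s <- fit$sds; w <- fit$weights
  f <- function(x) {
    log(w[1]) + dnorm(x, m[1], s[1], log = TRUE) -
      log(w[2]) - dnorm(x, m[2], s[2], log = TRUE)
  }
  if (abs(m[1] - m[2]) < 1e-12) return(NA_real_)
  root <- tryCatch(uniroot(f, sort(m), tol = 1e-10)$root,
                   error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  10^root
}
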