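# Independent oracles used to verify the package's implementations.
# These deliberately re-derive each quantity by brute force or closed
# form, sharing no code with the functions under test.

# Exhaustive spike scan: plain loop applying the acceleration + 0 mV
# criteria sample by sample.
oracle_spike_scan <- function(trace, accel_threshold = 20,
                              amplitude_gate = 0, confirm_ms = 10,
                              release_tol_mv = 0.5) {
  v <- trace$vm_mv
  t <- trace$t_ms
  dt <- t[2] - t[1]
  w <- round(confirm_ms / dt)
  n <- length(v)
  onsets <- numeric(0)
  i <- 2
  while (i <= n - 1) {
    a <- (v[i + 1] - 2 * v[i] + v[i - 1]) / dt^2
    if (a > accel_threshold) {
      win <- i:min(n, i + w)
      if (any(v[win] >= amplitude_gate)) {
        onsets <- c(onsets, t[i])
        j <- win[which(v[win] >= amplitude_gate)[1]]
        while (j <= n && v[j] >= v[i] + release_tol_mv) j <- j + 1
        i <- j
        next
      }
    }
    i <- i + 1
  }
  onsets
}

# Half-width of the planted spike template, recomputed from the
# continuous waveform by root finding.
oracle_template_width <- function(template) {
  f <- template$fun
  opt <- stats::optimize(f, c(1e-6, 50), maximum = TRUE)
  half <- opt$objective / 2
  up <- stats::uniroot(function(t) f(t) - half, c(1e-9, opt$maximum),
                       tol = 1e-12)$root
  dn <- stats::uniroot(function(t) f(t) - half, c(opt$maximum, 200),
                       tol = 1e-12)$root
  dn - up
}

# Two-sided Fisher exact p by direct hypergeometric enumeration
# (point-probability convention).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force re-implementation of the three-criterion trend rule.
oracle_trend_calls <- function(fpkm, samples, fold_cut = 3, q_cut = 0.05,
                               floor_fpkm = 10, pseudocount = 0.01) {
  div_of <- samples$div[match(colnames(fpkm), samples$sample_id)]
  divs <- sort(unique(div_of))
  res <- character(nrow(fpkm))
  ps <- numeric(nrow(fpkm))
  hi_i <- lo_i <- integer(nrow(fpkm))
  for (g in seq_len(nrow(fpkm))) {
    mns <- sapply(divs, function(d) mean(fpkm[g, div_of == d]))
    hi_i[g] <- which.max(mns)
    lo_i[g] <- which.min(mns)
    a <- fpkm[g, div_of == divs[hi_i[g]]]
    b <- fpkm[g, div_of == divs[lo_i[g]]]
    ps[g] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }
  qs <- oracle_bh(ps)
  for (g in seq_len(nrow(fpkm))) {
    mns <- sapply(divs, function(d) mean(fpkm[g, div_of == d]))
    fold <- (max(mns) + pseudocount) / (min(mns) + pseudocount)
    ok <- fold > fold_cut && qs[g] < q_cut && max(mns) > floor_fpkm
    res[g] <- if (!ok) "flat" else if (hi_i[g] > lo_i[g]) "increasing"
    else "decreasing"
  }
  res
}

# Exact Kruskal-Wallis permutation p by enumerating value permutations.
oracle_kw_exact <- function(values, groups) {
  h_of <- function(vv) unname(kruskal.test(vv, factor(groups))$statistic)
  h_obs <- h_of(values)
  perms <- combinat_permn(values)
  hs <- vapply(perms, h_of, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

combinat_permn <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permn(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# Helper building a one-track tibble from positions at 1 Hz.
track_tbl <- function(pos, t = seq_along(pos) - 1) {
  tibble::tibble(track_id = 1L, t_s = t, position_um = pos,
                 compartment = "axon")
}
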