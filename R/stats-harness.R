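# Test-selection logic used throughout the assays, with the branch taken
# recorded in `method_path` so every analysis is auditable.
#
# Two groups: Student's or Welch's t depending on an F-ratio variance
# check. More than two: one-way ANOVA; if Bartlett's test finds the
# equal-variance assumption violated the post hoc switches to
# Games-Howell, otherwise Bonferroni pairwise comparisons or Dunnett
# against a control. Regeneration ratios use Fisher's exact test with
# Bonferroni correction; patch-clamp group comparisons use
# Kruskal-Wallis.

test_result <- function(test_name, statistic, df, p, adjusted_p = NA_real_,
                        method_path = test_name, group1 = NA_character_,
                        group2 = NA_character_) {
  tibble::new_tibble(list(
    test_name = test_name, group1 = group1, group2 = group2,
    statistic = as.numeric(statistic), df = as.numeric(df),
    p = as.numeric(p), adjusted_p = as.numeric(adjusted_p),
    method_path = method_path), nrow = 1L)
}

#' Two-sample t test with automatic Student/Welch routing
#'
#' Variance equality is assessed by a two-sided F-ratio test at
#' `alpha_var`; equal variances route to Student's t, unequal to Welch's
#' t with Welch-Satterthwaite degrees of freedom. Zero variance in both
#' samples is handled by convention: p = 1 for equal means, p = 0
#' (flagged) for unequal means.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param alpha_var Significance level of the variance-equality gate.
#'
#' @return A one-row tibble (`test_name`, `statistic`, `df`, `p`,
#'   `method_path`).
#' @export
#' @examples
#' t_test_auto(rnorm(10), rnorm(10, 1))
t_test_auto <- function(a, b, alpha_var = 0.05) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2")
  if (any(!is.finite(c(a, b)))) abort("samples must be finite")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result("t_test", 0, NA_real_, 1,
                         method_path = "t_test/degenerate_equal"))
    }
    warn("zero variance in both samples with unequal means; p -> 0")
    return(test_result("t_test", Inf, NA_real_, 0,
                       method_path = "t_test/degenerate_unequal"))
  }
  vt_p <- var.test(a, b)$p.value
  equal <- vt_p >= alpha_var
  tt <- t.test(a, b, var.equal = equal)
  test_result(
    if (equal) "student_t" else "welch_t",
    unname(tt$statistic), unname(tt$parameter), tt$p.value,
    method_path = sprintf("t_test/F_p=%.4g/%s", vt_p,
                          if (equal) "student" else "welch")
  )
}

#' One-way ANOVA with selected post hoc comparisons
#'
#' Computes the one-way ANOVA F test and a post hoc procedure. In
#' `"auto"` mode, Bartlett's test at `alpha_var` gates the choice: when
#' the equal-variance assumption is significantly violated the
#' Games-Howell post hoc is used, otherwise the requested equal-variance
#' post hoc (`equal_var_posthoc`, Bonferroni pairwise by default, or
#' Dunnett against `control_group`).
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length as `values`; >= 3 groups for
#'   post hoc comparisons.
#' @param posthoc `"auto"`, `"bonferroni"`, `"dunnett"` or
#'   `"games_howell"`.
#' @param control_group Control level, required for Dunnett.
#' @param equal_var_posthoc Post hoc used on the equal-variance branch of
#'   `"auto"`.
#' @param alpha_var Significance level of Bartlett's gate.
#'
#' @return A list with `anova` (one-row tibble), `posthoc` (tibble of
#'   pairwise results) and `method_path`.
#' @export
anova_posthoc <- function(values, groups,
                          posthoc = c("auto", "bonferroni", "dunnett",
                                      "games_howell"),
                          control_group = NULL,
                          equal_var_posthoc = "bonferroni",
                          alpha_var = 0.05) {
  posthoc <- match.arg(posthoc)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  k <- length(unique(groups))
  if (k < 2) abort("need >= 2 groups")
  g <- factor(groups)
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  a_row <- test_result("one_way_anova", an$`F value`[1],
                       an$Df[1], an$`Pr(>F)`[1],
                       method_path = "anova")
  a_row$df2 <- an$Df[2]

  path <- "anova"
  chosen <- posthoc
  if (posthoc == "auto") {
    bt <- bartlett.test(values, g)
    violated <- bt$p.value < alpha_var
    chosen <- if (violated) "games_howell" else equal_var_posthoc
    path <- sprintf("anova/bartlett_p=%.4g/%s", bt$p.value, chosen)
  } else {
    path <- paste0("anova/", chosen)
  }

  ph <- switch(
    chosen,
    games_howell = games_howell(values, groups),
    bonferroni = bonferroni_pairwise(values, g),
    dunnett = dunnett_posthoc(values, g, control_group)
  )
  ph$method_path <- path
  list(anova = a_row, posthoc = ph, method_path = path)
}

bonferroni_pairwise <- function(values, g) {
  # pairwise t tests on the pooled ANOVA error, Bonferroni-adjusted
  lv <- levels(g)
  pairs <- combn(lv, 2)
  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  fit <- aov(values ~ g)
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfe <- summary(fit)[[1]]$Df[2]
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(mse * (1 / n[[g1]] + 1 / n[[g2]]))
    tt <- (m[[g1]] - m[[g2]]) / se
    p <- 2 * stats::pt(-abs(tt), dfe)
    test_result("bonferroni_t", tt, dfe, p,
                adjusted_p = min(1, p * ncol(pairs)),
                group1 = g1, group2 = g2)
  })
  dplyr::bind_rows(rows)
}

dunnett_posthoc <- function(values, g, control_group) {
  if (is.null(control_group)) abort("Dunnett requires `control_group`")
  if (!control_group %in% levels(g)) abort("unknown control group")
  g <- stats::relevel(g, ref = control_group)
  fit <- aov(values ~ g)
  # multcomp's multivariate-t integration is quasi-random; fix a seed so
  # repeated calls agree
  res <- with_seed(1L, {
    summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  })
  cmp <- res$test
  nm <- names(cmp$coefficients)
  rows <- lapply(seq_along(nm), function(i) {
    parts <- strsplit(nm[i], " - ", fixed = TRUE)[[1]]
    test_result("dunnett", unname(cmp$tstat[i]), res$df,
                p = NA_real_, adjusted_p = unname(cmp$pvalues[i]),
                group1 = parts[1], group2 = parts[2])
  })
  dplyr::bind_rows(rows)
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons robust to unequal variances: each pair uses the
#' Welch-type standard error and Welch-Satterthwaite degrees of freedom,
#' and the statistic `q = |mean difference| * sqrt(2) / SE` is referred
#' to the studentized range distribution with `k` groups.
#'
#' @param values Numeric response values.
#' @param groups Group labels (>= 2 groups, each with n >= 2).
#' @param df_floor Lower bound applied to the Welch degrees of freedom so
#'   the studentized-range integral stays defined for degenerate groups.
#'
#' @return A tibble of pairwise results with `statistic` (q), `df` and
#'   `p`.
#' @export
#' @examples
#' games_howell(c(rnorm(8), rnorm(8, 2)), rep(c("a", "b"), each = 8))
games_howell <- function(values, groups, df_floor = 2) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  k <- length(lv)
  if (k < 2) abort("need >= 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2)) abort("each group needs n >= 2")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  pairs <- combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se2 <- v[[g1]] / n[[g1]] + v[[g2]] / n[[g2]]
    flagged <- FALSE
    if (se2 <= 0) {
      # both variances zero: identical groups give p = 1, else p -> 0
      p <- if (m[[g1]] == m[[g2]]) 1 else 0
      return(test_result("games_howell", if (p == 1) 0 else Inf,
                         df_floor, p, group1 = g1, group2 = g2))
    }
    df <- se2^2 / (v[[g1]]^2 / (n[[g1]]^2 * (n[[g1]] - 1)) +
                     v[[g2]]^2 / (n[[g2]]^2 * (n[[g2]] - 1)))
    if (!is.finite(df) || df < df_floor) {
      df <- df_floor
      flagged <- TRUE
    }
    q <- abs(m[[g1]] - m[[g2]]) * sqrt(2) / sqrt(se2)
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    out <- test_result("games_howell", q, df, p, group1 = g1, group2 = g2)
    out$df_floored <- flagged
    out
  })
  dplyr::bind_rows(rows)
}

#' Fisher's exact test with Bonferroni correction
#'
#' Two-sided exact p for each 2x2 table by the point-probability
#' convention (the sum of hypergeometric probabilities of tables no more
#' likely than the observed one); larger tables fall back to a
#' Monte-Carlo p and are flagged. The Bonferroni-adjusted p multiplies by
#' the number of tables tested together.
#'
#' @param tables A list of integer matrices (contingency tables).
#' @param b Monte-Carlo replicates for r x c tables.
#' @param seed Seed for the Monte-Carlo fallback.
#'
#' @return A tibble with one row per table: `p`, `adjusted_p`,
#'   `monte_carlo`.
#' @export
#' @examples
#' fisher_exact_bonferroni(list(matrix(c(10, 2, 3, 9), 2)))
fisher_exact_bonferroni <- function(tables, b = 10000, seed = 1) {
  if (is.matrix(tables)) tables <- list(tables)
  m <- length(tables)
  p <- numeric(m)
  mc <- logical(m)
  for (i in seq_len(m)) {
    tab <- tables[[i]]
    if (!is.matrix(tab) || any(tab < 0) || any(tab != round(tab))) {
      abort(sprintf("table %d must hold nonnegative integer counts", i))
    }
    if (all(dim(tab) == c(2, 2))) {
      p[i] <- fisher.test(tab)$p.value
    } else {
      p[i] <- with_seed(seed + i, {
        fisher.test(tab, simulate.p.value = TRUE, B = b)$p.value
      })
      mc[i] <- TRUE
    }
  }
  tibble::new_tibble(list(
    test_name = rep("fisher_exact", m),
    group1 = rep(NA_character_, m), group2 = rep(NA_character_, m),
    statistic = rep(NA_real_, m), df = rep(NA_real_, m),
    p = p, adjusted_p = pmin(1, m * p),
    method_path = ifelse(mc, "fisher/monte_carlo", "fisher/exact"),
    monte_carlo = mc), nrow = m)
}

#' Kruskal-Wallis rank test
#'
#' The tie-corrected H statistic with a chi-square p (df = k - 1), used
#' for patch-clamp group comparisons in place of one-way ANOVA. For small
#' samples (`exact = TRUE`, total n <= 12) an exact permutation p is
#' computed by complete enumeration of group assignments.
#'
#' @param values Numeric response values.
#' @param groups Group labels.
#' @param exact Compute the exact permutation p (total n <= 12).
#'
#' @return A one-row tibble; `p` is the chi-square approximation and
#'   `p_exact` the enumeration value when requested.
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need >= 2 groups")
  if (length(unique(values)) == 1) {
    out <- test_result("kruskal_wallis", 0, length(unique(groups)) - 1, 1)
    out$p_exact <- NA_real_
    return(out)
  }
  kt <- kruskal.test(values, factor(groups))
  out <- test_result("kruskal_wallis", unname(kt$statistic),
                     unname(kt$parameter), kt$p.value)
  out$p_exact <- NA_real_
  if (exact) {
    n <- length(values)
    if (n > 12) abort("exact enumeration limited to total n <= 12")
    h_obs <- unname(kt$statistic)
    sizes <- table(groups)
    h_of <- function(perm_groups) {
      unname(kruskal.test(values, factor(perm_groups))$statistic)
    }
    perms <- all_group_assignments(names(sizes), as.integer(sizes))
    hs <- vapply(perms, h_of, numeric(1))
    out$p_exact <- mean(hs >= h_obs - 1e-12)
  }
  out
}

# Enumerate all distinct assignments of group labels to n slots.
all_group_assignments <- function(labels, sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(slots, lab_idx, acc) {
    if (lab_idx == length(labels)) {
      acc[slots] <- labels[lab_idx]
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (sel in as.list(as.data.frame(combn(slots, sizes[lab_idx])))) {
      acc2 <- acc
      acc2[sel] <- labels[lab_idx]
      recurse(setdiff(slots, sel), lab_idx + 1, acc2)
    }
  }
  recurse(seq_len(n), 1, character(n))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p values, monotone and capped at
#' 1, returned in input order.
#'
#' @param pvalues Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Log10 conversion for right-skewed measurements
#'
#' Retraction distances are log-normal, so group statistics are run on
#' log10-converted values. Non-positive entries are rejected with the
#' offending records named.
#'
#' @param values Positive numeric values.
#' @param ids Optional record identifiers used in error messages.
#' @return `log10(values)`.
#' @export
log10_transform <- function(values, ids = seq_along(values)) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0) {
    abort(sprintf("log10 undefined for non-positive values at: %s",
                  paste(ids[bad], collapse = ", ")))
  }
  log10(values)
}
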