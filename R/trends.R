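# Three-criterion classification of expression trends across the
# culture time course: a gene is increasing (decreasing) when (1) the
# highest timepoint mean exceeds 3x the lowest, (2) the FDR-adjusted p
# of Welch's t test between the extreme timepoints' replicates is below
# 0.05, and (3) at least one timepoint mean exceeds 10 FPKM.

#' Classify gene expression trends over the culture timepoints
#'
#' For each gene, timepoint means are computed over replicates; the fold
#' change compares the extreme timepoint means (with a pseudocount
#' guarding silent genes); Welch's t test runs between the replicate
#' values of the extreme timepoints; and Benjamini-Hochberg adjustment is
#' applied across all testable genes. A gene is increasing when all
#' three criteria hold and its maximal timepoint is later than its
#' minimal one, decreasing when earlier, flat otherwise. Ties in the
#' extreme timepoints are broken toward the earlier timepoint. The floor
#' criterion is evaluated on raw means (no pseudocount).
#'
#' @param fpkm Matrix of FPKM values, genes x samples, with dimnames.
#' @param samples Tibble mapping `sample_id` to `div` (timepoint) and
#'   `replicate`.
#' @param fold_cut Fold-change cut-off (criterion 1, strict >).
#' @param q_cut FDR-adjusted p cut-off (criterion 2, strict <).
#' @param floor_fpkm Expression floor (criterion 3, strict >).
#' @param pseudocount Added to both means in the fold ratio.
#'
#' @return A tibble per gene: `gene`, `class`, `fold`, `p`, `q`,
#'   `max_mean_fpkm`, `min_div`, `max_div`, `testable`.
#' @export
#' @examples
#' sim <- gen_expression_matrix(40, 4, 4, seed = 1)
#' calls <- classify_gene_trends(sim$fpkm, sim$samples)
#' table(calls$class)
classify_gene_trends <- function(fpkm, samples, fold_cut = 3,
                                 q_cut = 0.05, floor_fpkm = 10,
                                 pseudocount = 0.01) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)))
  if (!all(colnames(fpkm) %in% samples$sample_id)) {
    abort("every matrix column must appear in `samples`")
  }
  div_of <- samples$div[match(colnames(fpkm), samples$sample_id)]
  divs <- sort(unique(div_of))
  if (length(divs) < 2) abort("need >= 2 timepoints")
  reps_per <- table(div_of)
  untestable_tp <- names(reps_per)[reps_per < 2]

  n_genes <- nrow(fpkm)
  means <- vapply(divs, function(d) {
    rowMeans(fpkm[, div_of == d, drop = FALSE])
  }, numeric(n_genes))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)

  # ties break toward the earlier timepoint: which.max/min take the first
  i_max <- apply(means, 1, which.max)
  i_min <- apply(means, 1, which.min)
  max_mean <- means[cbind(seq_len(n_genes), i_max)]
  min_mean <- means[cbind(seq_len(n_genes), i_min)]
  fold <- (max_mean + pseudocount) / (min_mean + pseudocount)

  p <- rep(NA_real_, n_genes)
  testable <- rep(TRUE, n_genes)
  for (g in seq_len(n_genes)) {
    d_hi <- divs[i_max[g]]
    d_lo <- divs[i_min[g]]
    if (as.character(d_hi) %in% untestable_tp ||
        as.character(d_lo) %in% untestable_tp) {
      testable[g] <- FALSE
      next
    }
    a <- fpkm[g, div_of == d_hi]
    b <- fpkm[g, div_of == d_lo]
    p[g] <- welch_p(a, b)
  }
  if (any(!testable)) {
    warn(sprintf("%d gene(s) untestable: a timepoint has < 2 replicates",
                 sum(!testable)))
  }
  q <- rep(NA_real_, n_genes)
  q[testable] <- bh_adjust(p[testable])

  trending <- testable & fold > fold_cut & q < q_cut & max_mean > floor_fpkm
  class <- rep("flat", n_genes)
  class[!testable] <- NA_character_
  class[trending & i_max > i_min] <- "increasing"
  class[trending & i_max < i_min] <- "decreasing"

  tibble::tibble(
    gene = rownames(fpkm), class = class, fold = fold, p = p, q = q,
    max_mean_fpkm = max_mean, min_div = divs[i_min], max_div = divs[i_max],
    testable = testable
  )
}

welch_p <- function(a, b) {
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  se2 <- va / length(a) + vb / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  2 * stats::pt(-abs(tt), df)
}

#' Confusion matrix for trend calls against planted truth
#'
#' @param calls Tibble from [classify_gene_trends()].
#' @param truth Tibble with `gene` and planted `class`.
#'
#' @return A list: `confusion` (3x3 matrix, truth in rows), `by_class`
#'   (tibble of per-class sensitivity and specificity), `accuracy`.
#' @export
trend_confusion <- function(calls, truth) {
  if (!setequal(calls$gene, truth$gene)) {
    abort("calls and truth must cover the same genes")
  }
  m <- merge(truth, calls[, c("gene", "class")], by = "gene",
             suffixes = c("_truth", "_call"))
  lv <- c("increasing", "decreasing", "flat")
  conf <- table(factor(m$class_truth, lv), factor(m$class_call, lv))
  by_class <- dplyr::bind_rows(lapply(lv, function(cl) {
    tp <- sum(m$class_truth == cl & m$class_call == cl, na.rm = TRUE)
    fn <- sum(m$class_truth == cl & m$class_call != cl, na.rm = TRUE)
    fp <- sum(m$class_truth != cl & m$class_call == cl, na.rm = TRUE)
    tn <- sum(m$class_truth != cl & m$class_call != cl, na.rm = TRUE)
    tibble::tibble(class = cl,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  list(confusion = unclass(conf), by_class = by_class,
       accuracy = mean(m$class_truth == m$class_call, na.rm = TRUE))
}
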