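# Synthetic FPKM matrices over the culture time course with planted
# increasing / decreasing / flat genes.

#' Generate an FPKM matrix with planted expression trends
#'
#' Genes x samples FPKM over the five culture timepoints (1, 4, 8, 16,
#' 24 days in vitro) with six replicates each. Trending genes have
#' geometric (monotone) timepoint means spanning `fold`; their baseline
#' is drawn so the top timepoint clears the detection floor. Flat genes
#' cycle through three planted flavours that each violate one criterion
#' of the trend rule: constant means (no fold change), low expression
#' (fold above the cut-off but every mean below the floor), and high
#' within-group variance (criterion on the replicate test fails). Values
#' are log-normal around the planted means with coefficient of variation
#' `cv`.
#'
#' @param n_genes Total genes.
#' @param n_increasing,n_decreasing Planted trending genes.
#' @param fold Planted fold change (> 3) between extreme timepoints.
#' @param cv Within-timepoint coefficient of variation of trending and
#'   constant-flat genes.
#' @param floor_fpkm Expression floor used by the classifier; planted
#'   low-expression flat genes stay below it.
#' @param n_reps Replicates per timepoint.
#' @param seed Integer seed.
#'
#' @return A list with `fpkm` (matrix, genes x samples), `samples`
#'   (tibble: `sample_id`, `div`, `replicate`) and `truth` (tibble:
#'   `gene`, `class`).
#' @export
#' @examples
#' sim <- gen_expression_matrix(50, 5, 5, seed = 2)
#' table(sim$truth$class)
gen_expression_matrix <- function(n_genes, n_increasing, n_decreasing,
                                  fold = 5, cv = 0.1, floor_fpkm = 10,
                                  n_reps = 6, seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1)
  n_increasing <- assert_count(n_increasing, "n_increasing")
  n_decreasing <- assert_count(n_decreasing, "n_decreasing")
  if (n_increasing + n_decreasing > n_genes) {
    abort("trending genes cannot exceed `n_genes`")
  }
  if (fold <= 3) abort("planted trending genes need fold > 3")
  divs <- c(1, 4, 8, 16, 24)
  n_tp <- length(divs)
  samples <- tibble::tibble(
    sample_id = sprintf("DIV%02d_r%d", rep(divs, each = n_reps),
                        rep(seq_len(n_reps), n_tp)),
    div = rep(divs, each = n_reps),
    replicate = rep(seq_len(n_reps), n_tp)
  )
  n_flat <- n_genes - n_increasing - n_decreasing
  classes <- c(rep("increasing", n_increasing),
               rep("decreasing", n_decreasing),
               rep("flat", n_flat))

  with_seed(seed, {
    classes <- sample(classes)
    genes <- sprintf("gene%05d", seq_len(n_genes))
    fpkm <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
    flat_flavours <- c("constant", "low", "noisy")
    flav_i <- 0
    for (g in seq_len(n_genes)) {
      cls <- classes[g]
      gene_cv <- cv
      if (cls == "increasing" || cls == "decreasing") {
        base <- runif(1, 1.2 * floor_fpkm / fold, 2.5 * floor_fpkm / fold)
        means <- base * fold^(seq(0, 1, length.out = n_tp))
        if (cls == "decreasing") means <- rev(means)
      } else {
        flav_i <- flav_i + 1
        flavour <- flat_flavours[(flav_i - 1) %% 3 + 1]
        means <- switch(
          flavour,
          constant = rep(runif(1, 0.5 * floor_fpkm, 5 * floor_fpkm), n_tp),
          low = {
            l <- runif(1, 0.05, 0.2) * floor_fpkm
            l * 3.5^(seq(0, 1, length.out = n_tp))
          },
          noisy = {
            gene_cv <- 1.2
            rep(runif(1, 1.5 * floor_fpkm, 4 * floor_fpkm), n_tp)
          }
        )
      }
      sigma <- sqrt(log(1 + gene_cv^2))
      mu <- log(rep(means, each = n_reps)) - sigma^2 / 2
      fpkm[g, ] <- stats::rlnorm(n_tp * n_reps, mu, sigma)
    }
    list(fpkm = fpkm, samples = samples,
         truth = tibble::tibble(gene = genes, class = classes))
  })
}
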