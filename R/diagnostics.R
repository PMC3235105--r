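#' Per-gene z-normalization across arrays
#'
#' Centers and scales each gene's log2 expression so that its mean and
#' standard deviation across all arrays are 0 and 1, the transformation used
#' to inspect oscillating profiles on a common scale. The population
#' standard deviation (divisor `n`) is the default, so a two-array gene maps
#' to (-1, +1); the sample convention (divisor `n - 1`) is available.
#' Constant genes cannot be scaled and are dropped with a message.
#'
#' @param matrix Genes x arrays log2 expression matrix with >= 2 columns.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The z-scored matrix (possibly with fewer rows); dropped gene ids
#'   are attached as attribute `"dropped"`.
#' @export
z_normalize <- function(matrix, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2) stop("z-normalization needs >= 2 arrays")
  mu <- rowMeans(matrix)
  centered <- matrix - mu
  ss <- rowSums(centered^2)
  denom <- if (sd_type == "population") ncol(matrix) else ncol(matrix) - 1L
  s <- sqrt(ss / denom)
  constant <- s == 0
  if (all(constant)) stop("all genes are constant; nothing to normalize")
  if (any(constant)) {
    message(sum(constant), " constant gene(s) dropped from z-normalization")
  }
  z <- centered[!constant, , drop = FALSE] / s[!constant]
  attr(z, "dropped") <- rownames(matrix)[constant]
  z
}

#' Group-mean z-score profiles
#'
#' Arithmetic mean of the z-scores within each (tissue, stage) sample group,
#' per gene -- the bar heights of the oscillation-inspection plots, where
#' whole-embryo bars below 0 against limb bars above 0 indicate genuinely
#' limb-driven oscillation.
#'
#' @param z Z-scored matrix from [z_normalize()].
#' @param sheet Sample sheet covering the matrix columns.
#' @return Genes x groups matrix; group columns are named
#'   `<tissue>.<stage>`.
#' @export
group_mean_profiles <- function(z, sheet) {
  sheet <- sheet[sheet$array_id %in% colnames(z), , drop = FALSE]
  groups <- unique(sheet[, c("tissue", "stage")])
  if (!nrow(groups)) stop("no sample groups cover the matrix columns")
  out <- matrix(NA_real_, nrow(z), nrow(groups),
                dimnames = list(rownames(z),
                                paste(groups$tissue, groups$stage, sep = ".")))
  for (i in seq_len(nrow(groups))) {
    arrays <- sheet$array_id[sheet$tissue == groups$tissue[i] &
                               sheet$stage == groups$stage[i]]
    if (!length(arrays)) stop("empty sample group")
    out[, i] <- rowMeans(z[, arrays, drop = FALSE])
  }
  out
}

#' @noRd
rank_sum_stat <- function(ranks, idx) sum(ranks[idx])

#' Wilcoxon rank-sum test (midranks, exact for small samples)
#'
#' Two-sided Wilcoxon rank-sum test on the rank sum `W` of `x`, using
#' midranks for ties. For `length(x) + length(y) <= exact_max_n` the null
#' distribution of `W` is enumerated exactly over all assignments of the
#' (mid)ranks to the two groups and the p-value is
#' `P(|W' - E[W]| >= |W - E[W]|)`; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max_n Largest combined sample size for exact enumeration.
#' @return List with elements `statistic` (the rank sum of `x`), `p.value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  ranks <- rank(c(x, y))  # midranks for ties
  w <- sum(ranks[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max_n) {
    idx_sets <- utils::combn(n, nx)
    ws <- colSums(array(ranks[idx_sets], dim = dim(idx_sets)))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    return(list(statistic = w, p.value = p, method = "exact"))
  }
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
  z <- (abs(w - mu) - 0.5) / sqrt(v)
  list(statistic = w, p.value = min(1, 2 * pnorm(-z)), method = "normal")
}

#' False-negative screen against a phenotype gene list
#'
#' Quantifies how many genes from an externally curated phenotype list (e.g.
#' genes whose mutants show abnormal limb morphology) are recovered as
#' up-regulated in at least one limb-versus-control comparison, and whether
#' the missed genes are expressed lower in the limb than the recovered ones
#' -- the signature of false negatives caused by low limb expression rather
#' than by whole-embryo differences. Four Wilcoxon rank-sum comparisons are
#' reported: missed versus recovered phenotype genes, and missed phenotype
#' genes versus all array genes, each on mean limb expression and on mean
#' whole-embryo expression.
#'
#' @param de DE table from [run_all_contrasts()].
#' @param matrix Genes x arrays log2 expression matrix.
#' @param sheet Sample sheet.
#' @param phenotype_genes Character vector of phenotype gene ids; must
#'   overlap the array genes.
#' @return List of class `"fn_report"`: `n_phenotype`, `n_on_array`, `n_up`,
#'   `fraction_up`, `wilcoxon` (data.frame of the four comparisons with
#'   `NA` p-values where a group is empty), and `expression_summary`
#'   (quantiles of limb and whole-embryo expression per gene group).
#' @export
false_negative_report <- function(de, matrix, sheet, phenotype_genes) {
  on_array <- intersect(phenotype_genes, rownames(matrix))
  if (!length(on_array)) stop("phenotype list is disjoint from the array genes")
  limb_arrays <- sheet$array_id[sheet$tissue %in% c("forelimb", "hindlimb")]
  we_arrays <- sheet$array_id[sheet$tissue == "whole_embryo"]
  limb_expr <- rowMeans(matrix[, intersect(limb_arrays, colnames(matrix)), drop = FALSE])
  we_expr <- rowMeans(matrix[, intersect(we_arrays, colnames(matrix)), drop = FALSE])

  limb_de <- de[de$type == "limb_vs_we", , drop = FALSE]
  up_genes <- unique(limb_de$gene[limb_de$call == "up"])
  pheno_up <- intersect(on_array, up_genes)
  pheno_not_up <- setdiff(on_array, up_genes)

  run_test <- function(a, b) {
    if (!length(a) || !length(b)) return(NA_real_)
    wilcoxon_rank_sum(a, b)$p.value
  }
  wil <- data.frame(
    comparison = c("not_up_vs_up_phenotype", "not_up_vs_up_phenotype",
                   "not_up_vs_all_genes", "not_up_vs_all_genes"),
    compartment = c("limb", "whole_embryo", "limb", "whole_embryo"),
    p = c(run_test(limb_expr[pheno_not_up], limb_expr[pheno_up]),
          run_test(we_expr[pheno_not_up], we_expr[pheno_up]),
          run_test(limb_expr[pheno_not_up], limb_expr),
          run_test(we_expr[pheno_not_up], we_expr)),
    stringsAsFactors = FALSE
  )
  qs <- function(v) if (length(v)) quantile(v, c(0, .25, .5, .75, 1)) else rep(NA_real_, 5)
  summary <- rbind(
    limb_not_up = qs(limb_expr[pheno_not_up]),
    limb_up = qs(limb_expr[pheno_up]),
    limb_all = qs(limb_expr),
    we_not_up = qs(we_expr[pheno_not_up]),
    we_up = qs(we_expr[pheno_up]),
    we_all = qs(we_expr)
  )
  structure(list(
    n_phenotype = length(phenotype_genes),
    n_on_array = length(on_array),
    n_up = length(pheno_up),
    fraction_up = length(pheno_up) / length(on_array),
    wilcoxon = wil,
    expression_summary = summary
  ), class = "fn_report")
}

#' @export
print.fn_report <- function(x, ...) {
  cat("Phenotype-list false-negative screen\n")
  cat(sprintf("  on array: %d / %d; up-regulated in >=1 comparison: %d (%.1f%%)\n",
              x$n_on_array, x$n_phenotype, x$n_up, 100 * x$fraction_up))
  print(x$wilcoxon)
  invisible(x)
}

#' Flag genes with low limb expression at every stage
#'
#' Genes whose mean limb (forelimb plus hindlimb) log2 expression is below
#' `threshold` at each of the five developmental stages -- candidates for
#' limb genes the limb-versus-control screen cannot detect.
#'
#' @param matrix Genes x arrays log2 expression matrix.
#' @param sheet Sample sheet; limb samples must exist at every stage.
#' @param threshold Log2 expression cut-off (default 5).
#' @return Sorted character vector of flagged gene ids.
#' @export
low_expression_flags <- function(matrix, sheet, threshold = 5) {
  stages <- limb_stages()
  flagged <- rep(TRUE, nrow(matrix))
  for (s in stages) {
    arrays <- sheet$array_id[sheet$tissue %in% c("forelimb", "hindlimb") &
                               sheet$stage == s]
    arrays <- intersect(arrays, colnames(matrix))
    if (!length(arrays)) stop("no limb samples at stage ", s)
    flagged <- flagged & rowMeans(matrix[, arrays, drop = FALSE]) < threshold
  }
  sort(rownames(matrix)[flagged])
}
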