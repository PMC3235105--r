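#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) to share the same empirical distribution: the
#' vector of row-wise means of the sorted input columns, assigned back in each
#' column's original rank order. This is the normalization step of the RMA
#' protocol. Tied values within a column receive the mean of the reference
#' values at their tied ranks. The operation is idempotent.
#'
#' @param matrix Genes x arrays numeric matrix (log2 scale) with >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- cbind(a = c(1, 3), b = c(2, 6))
#' quantile_normalize(m)  # both columns become (1.5, 4.5)
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (ncol(matrix) < 2) {
    stop("quantile normalization needs >= 2 arrays (nothing to normalize against)")
  }
  if (!all(is.finite(matrix))) stop("expression matrix contains non-finite values")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Summarize probe-level intensities to gene level by median polish
#'
#' RMA's summarization step: for each gene, Tukey's median polish is run on
#' its probes x arrays submatrix (iterative row/column median sweeps until
#' residual row and column medians fall below `tol` or `max_iter` sweeps),
#' and the gene's value on each array is the fitted overall effect plus that
#' array's column effect. Probe (row) effects absorb probe-specific
#' affinities. Single-probe genes pass through unchanged.
#'
#' @param probe_matrix Probes x arrays numeric matrix on the log2 scale.
#' @param map Data frame with columns `probe`, `gene`; many-to-one, covering
#'   every row of `probe_matrix`.
#' @param max_iter Maximum number of polish sweeps.
#' @param tol Convergence tolerance on the residual medians.
#' @return Genes x arrays matrix of summarized log2 expression.
#' @export
median_polish_summarize <- function(probe_matrix, map, max_iter = 10L, tol = 1e-6) {
  stopifnot(is.matrix(probe_matrix), is.data.frame(map),
            all(c("probe", "gene") %in% names(map)))
  if (anyDuplicated(map$probe)) stop("probe map is not many-to-one")
  unmapped <- setdiff(rownames(probe_matrix), map$probe)
  if (length(unmapped)) {
    stop("probes missing from map: ", paste(utils::head(unmapped, 3), collapse = ", "))
  }
  gene_of <- setNames(map$gene, map$probe)[rownames(probe_matrix)]
  genes <- unique(gene_of)
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  rows_by_gene <- split(seq_len(nrow(probe_matrix)), gene_of)
  for (g in genes) {
    rows <- rows_by_gene[[g]]
    if (!length(rows)) stop("gene with zero probes: ", g)
    sub <- probe_matrix[rows, , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[g, ] <- sub[1L, ]
    } else {
      out[g, ] <- polish_summary(sub, max_iter, tol)
    }
  }
  out
}

# One gene's polish: alternating row/column median sweeps until the
# residual row and column medians drop below tol (or max_iter sweeps),
# returning overall + column effects. The stopping rule is on the residual
# medians themselves, not on the change in total absolute residual.
#' @noRd
polish_summary <- function(x, max_iter, tol) {
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  for (iter in seq_len(max_iter)) {
    rmed <- apply(x, 1L, median)
    x <- x - rmed
    row_eff <- row_eff + rmed
    cmed <- apply(x, 2L, median)
    x <- sweep(x, 2L, cmed)
    col_eff <- col_eff + cmed
    shift <- median(row_eff)
    row_eff <- row_eff - shift
    overall <- overall + shift
    shift <- median(col_eff)
    col_eff <- col_eff - shift
    overall <- overall + shift
    if (max(abs(apply(x, 1L, median))) < tol &&
        max(abs(apply(x, 2L, median))) < tol) break
  }
  overall + col_eff
}

#' Repair a blemish on one array by replicate-median substitution
#'
#' Replaces the values of `flagged_genes` on `flagged_array` with the median
#' of the same gene across the array's replicate group (same tissue and
#' stage, excluding the flagged array itself), the reference-value repair
#' applied to a damaged whole-embryo control. All other cells are untouched,
#' and re-running the repair is idempotent.
#'
#' @param matrix Genes x arrays expression matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param flagged_array Array id of the blemished array.
#' @param flagged_genes Character vector of affected gene ids.
#' @return The repaired matrix.
#' @export
repair_blemish <- function(matrix, sheet, flagged_array, flagged_genes) {
  stopifnot(is.matrix(matrix))
  if (!flagged_array %in% colnames(matrix)) {
    stop("flagged array not in matrix: ", flagged_array)
  }
  if (!length(flagged_genes)) return(matrix)
  missing <- setdiff(flagged_genes, rownames(matrix))
  if (length(missing)) {
    stop("flagged gene(s) not in matrix: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  row <- sheet[sheet$array_id == flagged_array, , drop = FALSE]
  if (nrow(row) != 1L) stop("flagged array not in sample sheet: ", flagged_array)
  mates <- sheet$array_id[sheet$tissue == row$tissue & sheet$stage == row$stage &
                            sheet$array_id != flagged_array]
  mates <- intersect(mates, colnames(matrix))
  if (!length(mates)) {
    stop("no replicate available to repair array ", flagged_array)
  }
  ref <- apply(matrix[flagged_genes, mates, drop = FALSE], 1L, median)
  matrix[flagged_genes, flagged_array] <- ref
  matrix
}
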