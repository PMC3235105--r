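#' @noRd
up_by_stage <- function(de, tissue) {
  sub <- de[de$type == "limb_vs_we" & de$tissue == tissue, , drop = FALSE]
  split(setNames(sub$call == "up", sub$gene), sub$stage)
}

# "not up-regulated" means call != up (down and unchanged both qualify);
# a veto referring to a stage with no contrast is skipped.
#' @noRd
veto <- function(up_list, stage, genes) {
  if (is.null(stage) || is.na(stage) || is.null(up_list[[stage]])) {
    return(rep(FALSE, length(genes)))
  }
  v <- up_list[[stage]][genes]
  v[is.na(v)] <- FALSE
  v
}

#' Forelimb-specific genes at a stage (delay-adjusted)
#'
#' Hindlimb development lags the forelimb by roughly half a day, so a gene is
#' called forelimb-specific at a stage when it is up-regulated in the
#' forelimb versus the time-matched control, not up-regulated in the
#' hindlimb at the same stage, and not up-regulated in the hindlimb at the
#' subsequent stage (the delay veto). Vetoes that refer to missing contrasts
#' -- the same-stage hindlimb at E9.5, or the subsequent stage beyond E13.5
#' -- are skipped, leaving the remaining conditions in force.
#'
#' @param de DE table from [run_all_contrasts()].
#' @param stage Stage label at which to call forelimb specificity.
#' @return Sorted character vector of forelimb-specific genes.
#' @export
forelimb_specific <- function(de, stage) {
  stages <- limb_stages()
  pos <- match(stage, stages)
  if (is.na(pos)) stop("unknown stage: ", stage)
  fl_up <- up_by_stage(de, "forelimb")
  if (is.null(fl_up[[stage]])) stop("no forelimb contrast at ", stage)
  hl_up <- up_by_stage(de, "hindlimb")
  genes <- names(fl_up[[stage]])[fl_up[[stage]]]
  next_stage <- if (pos < length(stages)) stages[pos + 1L] else NA_character_
  keep <- !veto(hl_up, stage, genes) & !veto(hl_up, next_stage, genes)
  sort(genes[keep])
}

#' Hindlimb-specific genes at a stage (delay-adjusted)
#'
#' The mirror of [forelimb_specific()]: genes up-regulated in the hindlimb
#' versus the time-matched control, not up-regulated in the forelimb at the
#' same stage, and not up-regulated in the forelimb at the preceding stage
#' (because the forelimb runs ahead of the hindlimb). Requires hindlimb data
#' at the stage, so E9.5 is an error by design.
#'
#' @inheritParams forelimb_specific
#' @return Sorted character vector of hindlimb-specific genes.
#' @export
hindlimb_specific <- function(de, stage) {
  stages <- limb_stages()
  pos <- match(stage, stages)
  if (is.na(pos)) stop("unknown stage: ", stage)
  hl_up <- up_by_stage(de, "hindlimb")
  if (is.null(hl_up[[stage]])) stop("no hindlimb contrast at ", stage)
  fl_up <- up_by_stage(de, "forelimb")
  genes <- names(hl_up[[stage]])[hl_up[[stage]]]
  prev_stage <- if (pos > 1L) stages[pos - 1L] else NA_character_
  keep <- !veto(fl_up, stage, genes) & !veto(fl_up, prev_stage, genes)
  sort(genes[keep])
}

#' Identity calls across all stages
#'
#' Convenience wrapper applying [forelimb_specific()] and
#' [hindlimb_specific()] at every stage with the required contrasts.
#'
#' @param de DE table from [run_all_contrasts()].
#' @return Data frame with columns `gene`, `side`, `stage`.
#' @export
limb_identity_calls <- function(de) {
  out <- list()
  for (stage in intersect(limb_stages(), unique(de$stage))) {
    fl <- tryCatch(forelimb_specific(de, stage), error = function(e) character())
    hl <- tryCatch(hindlimb_specific(de, stage), error = function(e) character())
    if (length(fl)) {
      out[[length(out) + 1L]] <- data.frame(gene = fl, side = "forelimb",
                                            stage = stage, stringsAsFactors = FALSE)
    }
    if (length(hl)) {
      out[[length(out) + 1L]] <- data.frame(gene = hl, side = "hindlimb",
                                            stage = stage, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), side = character(), stage = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Direct forelimb-versus-hindlimb differential expression at one stage
#'
#' Moderated-t contrast of forelimb against hindlimb arrays at a shared
#' stage. Genes with fold change at least `fc_threshold` and adjusted
#' p-value below `p_threshold` are labelled forelimb-enriched; genes with
#' fold change at most the reciprocal, hindlimb-enriched. Swapping the
#' tissue labels swaps the enriched sides exactly.
#'
#' @param matrix Genes x arrays log2 expression matrix.
#' @param sheet Sample sheet.
#' @param stage Stage with both limb tissues sampled.
#' @param fc_threshold,p_threshold Enrichment thresholds.
#' @param moderation Optional `"moderation_params"` override; by default the
#'   hyperparameters are estimated from this contrast's gene variances.
#' @return A DE-table data.frame for the single contrast with an extra
#'   `side` column (`"forelimb"`, `"hindlimb"`, or `NA` for unenriched).
#' @export
interlimb_de <- function(matrix, sheet, stage, fc_threshold = 2,
                         p_threshold = 0.001, moderation = NULL) {
  nm <- paste0("FLvHL_", stage)
  def <- contrast_def(nm, "forelimb", stage, "hindlimb", stage)
  fit <- fit_gene_stats(matrix, sheet, def)
  par <- if (is.null(moderation)) {
    tryCatch(estimate_moderation(fit$s2, fit$df[1]), error = function(e) NULL)
  } else {
    moderation
  }
  if (is.null(par)) {
    # noise-free degenerate input: certainty rule as in run_all_contrasts
    mt <- data.frame(t_mod = ifelse(fit$log2fc == 0, 0, sign(fit$log2fc) * Inf),
                     df_total = NA_real_,
                     p = ifelse(fit$log2fc == 0, 1, 0),
                     degenerate = TRUE)
  } else {
    mt <- moderated_t(fit$log2fc, fit$s2, fit$df, fit$v, par)
  }
  p <- mt$p
  p[mt$degenerate & fit$log2fc == 0] <- 1
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- benjamini_hochberg(p[ok])
  fc <- 2^fit$log2fc
  call <- call_status(fc, adj, fc_threshold, p_threshold)
  data.frame(
    gene = fit$gene, contrast = nm, type = "fl_vs_hl",
    tissue = NA_character_, stage = stage,
    mean_A = fit$mean_A, mean_B = fit$mean_B,
    log2fc = fit$log2fc, fc = fc,
    t_mod = mt$t_mod, df = mt$df_total, p = p, adj_p = adj, call = call,
    side = ifelse(call == "up", "forelimb",
                  ifelse(call == "down", "hindlimb", NA_character_)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
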