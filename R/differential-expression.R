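#' Define a two-group contrast
#'
#' @param name Contrast label used in result tables.
#' @param tissue_a,stage_a Tissue and stage of group A (the numerator of the
#'   fold change, e.g. the limb sample).
#' @param tissue_b,stage_b Tissue and stage of group B (the denominator,
#'   e.g. the time-matched whole-embryo control).
#' @return A list of class `"contrast_def"`.
#' @export
contrast_def <- function(name, tissue_a, stage_a, tissue_b, stage_b) {
  structure(list(name = name,
                 a = list(tissue = tissue_a, stage = stage_a),
                 b = list(tissue = tissue_b, stage = stage_b)),
            class = "contrast_def")
}

#' @noRd
contrast_arrays <- function(sheet, group) {
  sheet$array_id[sheet$tissue == group$tissue & sheet$stage == group$stage]
}

#' Per-gene two-group statistics for one contrast
#'
#' The linear-model stage of the moderated-t pipeline: for each gene, the
#' group means on the log2 scale, their difference (the log2 fold change,
#' group A minus group B), the pooled two-sample variance with
#' `nA + nB - 2` residual degrees of freedom, and the contrast variance
#' factor `1/nA + 1/nB`.
#'
#' @param matrix Genes x arrays log2 expression matrix.
#' @param sheet Sample sheet mapping arrays to (tissue, stage).
#' @param contrast A [contrast_def()]; both groups must have >= 2 arrays.
#' @return A data.frame with columns `gene`, `mean_A`, `mean_B`, `log2fc`,
#'   `s2` (pooled variance), `df` (residual degrees of freedom) and `v`
#'   (variance factor), plus attribute `"contrast"`.
#' @export
fit_gene_stats <- function(matrix, sheet, contrast) {
  stopifnot(inherits(contrast, "contrast_def"))
  a <- intersect(contrast_arrays(sheet, contrast$a), colnames(matrix))
  b <- intersect(contrast_arrays(sheet, contrast$b), colnames(matrix))
  if (length(intersect(a, b))) stop("contrast groups overlap")
  if (length(a) < 2 || length(b) < 2) {
    stop("contrast ", contrast$name, ": each group needs >= 2 arrays")
  }
  xa <- matrix[, a, drop = FALSE]
  xb <- matrix[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  out <- data.frame(
    gene = rownames(matrix),
    mean_A = ma, mean_B = mb,
    log2fc = ma - mb,
    s2 = (ssa + ssb) / df,
    df = df,
    v = 1 / na + 1 / nb,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast$name
  out
}

# Inverse of the trigamma function by monotone root finding: trigamma is
# strictly decreasing on (0, Inf) with range (0, Inf), so a sign change is
# bracketed between tiny and huge arguments.
#' @noRd
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > trigamma(1e-8)) return(1e-8)
    if (xi < trigamma(1e8)) return(Inf)
    uniroot(function(y) trigamma(y) - xi,
            lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  }, numeric(1))
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-statistic by
#' matching moments of the log sample variances `e_g = log(s2_g)`. The prior
#' degrees of freedom `d0` solve
#' `trigamma(d0/2) = var(e_g) - mean(trigamma(df_g/2))` by monotone root
#' finding; the prior variance `s0_sq` follows from the mean of `e_g` with
#' the digamma bias correction. When the right-hand side is non-positive the
#' variances show no excess dispersion beyond chi-square sampling scatter:
#' `d0 = Inf` and `s0_sq` is the plain mean of the sample variances.
#'
#' @param s2 Numeric vector of pooled per-gene sample variances. Genes with
#'   zero or non-finite variance are excluded from estimation.
#' @param df Residual degrees of freedom, scalar or per-gene vector.
#' @return A list of class `"moderation_params"` with elements `d0` (prior
#'   degrees of freedom, possibly `Inf`) and `s0_sq` (prior variance),
#'   plus `n_used`, the number of genes entering the fit.
#' @export
estimate_moderation <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (!any(ok)) stop("all gene variances are zero or unusable (degenerate input)")
  if (sum(ok) < 10L) stop("need >= 10 genes with positive variance to estimate moderation")
  e <- log(s2[ok])
  dfo <- df[ok]
  # e_g has mean log(s0^2) + E[log chi2_df/df] - E[log chi2_d0/d0] and
  # variance trigamma(df/2) + trigamma(d0/2)
  rhs <- var(e) - mean(trigamma(dfo / 2))
  bias_df <- mean(digamma(dfo / 2) - log(dfo / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    # no excess dispersion beyond chi-square sampling scatter: the genes
    # share one variance, estimated by the plain mean
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(mean(e) - bias_df + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = sum(ok)),
            class = "moderation_params")
}

#' Construct moderation parameters directly
#'
#' @param d0 Prior degrees of freedom (>= 0; may be `Inf`).
#' @param s0_sq Prior variance (> 0).
#' @return A `"moderation_params"` object.
#' @export
moderation_params <- function(d0, s0_sq) {
  if (d0 < 0) stop("d0 must be >= 0")
  if (s0_sq <= 0) stop("s0_sq must be > 0")
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = NA_integer_),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat("Moderation parameters: d0 =", format(x$d0),
      " s0_sq =", format(x$s0_sq), "\n")
  invisible(x)
}

#' Moderated t-statistics from shrunken variances
#'
#' Shrinks each gene's sample variance toward the prior,
#' `s_post^2 = (d0 * s0^2 + df * s2) / (d0 + df)` (the limit `s0^2` as
#' `d0 -> Inf`), and forms `t = log2fc / sqrt(s_post^2 * v)` with
#' `d0 + df` total degrees of freedom and a two-sided Student-t p-value.
#' With `d0 = 0` this reduces to the ordinary pooled two-sample t-test.
#'
#' @param log2fc,s2,df,v Per-gene statistics as from [fit_gene_stats()].
#' @param params A `"moderation_params"` object.
#' @return A data.frame with columns `t_mod`, `df_total`, `p`, and
#'   `degenerate` (TRUE where the posterior variance is zero, leaving the
#'   p-value undefined: such genes get `t_mod = NA`, `p = NA`).
#' @export
moderated_t <- function(log2fc, s2, df, v, params) {
  stopifnot(inherits(params, "moderation_params"))
  d0 <- params$d0; s0 <- params$s0_sq
  if (is.infinite(d0)) {
    s_post <- rep(s0, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  degenerate <- s_post <= 0
  t_mod <- ifelse(degenerate, NA_real_, log2fc / sqrt(s_post * v))
  p <- ifelse(degenerate, NA_real_, 2 * pt(-abs(t_mod), df = df_total))
  data.frame(t_mod = t_mod, df_total = df_total, p = p,
             degenerate = degenerate, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `adj_p_(i) = min_{j >= i} (n * p_(j) / j)`, capped at 1 and mapped back
#' to the input order. Controls the false discovery rate at the level at
#' which the adjusted values are thresholded.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential-expression status from fold change and adjusted p
#'
#' A gene is called `"up"` when its fold change is at least `fc_threshold`
#' with adjusted p-value below `p_threshold`, `"down"` when the fold change
#' is at most `1/fc_threshold` at the same significance, and `"unchanged"`
#' otherwise. With the defaults this is the calling rule "fold change 2 or
#' greater with adjusted p < 0.001"; a fold change of 1 (log2 FC 0) always
#' means no change.
#'
#' @param fc Positive fold changes (`2^log2fc`).
#' @param adj_p Adjusted p-values.
#' @param fc_threshold Fold-change threshold (> 1).
#' @param p_threshold Adjusted-p threshold.
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
call_status <- function(fc, adj_p, fc_threshold = 2, p_threshold = 0.001) {
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  out <- rep("unchanged", length(fc))
  sig <- !is.na(adj_p) & adj_p < p_threshold
  out[sig & fc >= fc_threshold] <- "up"
  out[sig & fc <= 1 / fc_threshold] <- "down"
  out
}

#' @noRd
standard_contrasts <- function(sheet) {
  stages <- intersect(limb_stages(), unique(sheet$stage))
  defs <- list()
  have <- function(tissue, stage) {
    sum(sheet$tissue == tissue & sheet$stage == stage) >= 2
  }
  for (s in stages) {
    for (tissue in c("forelimb", "hindlimb")) {
      if (have(tissue, s) && have("whole_embryo", s)) {
        nm <- paste0(tissue_code[[tissue]], "_", s)
        defs[[nm]] <- list(def = contrast_def(nm, tissue, s, "whole_embryo", s),
                           type = "limb_vs_we", tissue = tissue, stage = s)
      }
    }
    if (have("forelimb", s) && have("hindlimb", s)) {
      nm <- paste0("FLvHL_", s)
      defs[[nm]] <- list(def = contrast_def(nm, "forelimb", s, "hindlimb", s),
                         type = "fl_vs_hl", tissue = NA_character_, stage = s)
    }
  }
  defs
}

#' Run the full set of study contrasts
#'
#' Builds and fits every standard contrast supported by the sample sheet:
#' each limb tissue versus the time-matched whole-embryo control at every
#' stage with data (forelimb at all five stages, hindlimb from its first
#' sampled stage), plus direct forelimb-versus-hindlimb contrasts at shared
#' stages. Moderation hyperparameters are estimated once per residual
#' degrees-of-freedom value by pooling gene variances across the contrasts
#' that share it; Benjamini-Hochberg adjustment is applied per contrast.
#' Contrasts whose groups lack replication are skipped with a warning.
#'
#' @param matrix Genes x arrays log2 expression matrix.
#' @param sheet Sample sheet.
#' @param fc_threshold,p_threshold Calling thresholds (see [call_status()]).
#' @param moderation Optional `"moderation_params"` override applied to all
#'   contrasts instead of pooled estimation.
#' @return A long-format data.frame (the DE table), one row per gene and
#'   contrast: `gene`, `contrast`, `type`, `tissue`, `stage`, `mean_A`,
#'   `mean_B`, `log2fc`, `fc`, `t_mod`, `df`, `p`, `adj_p`, `call`. The
#'   moderation parameters used are attached as attribute `"moderation"`.
#' @export
run_all_contrasts <- function(matrix, sheet, fc_threshold = 2,
                              p_threshold = 0.001, moderation = NULL) {
  defs <- standard_contrasts(sheet)
  if (!length(defs)) stop("sample sheet supports no standard contrast")
  fits <- list()
  for (nm in names(defs)) {
    fit <- tryCatch(fit_gene_stats(matrix, sheet, defs[[nm]]$def),
                    error = function(e) {
                      warning("skipping contrast ", nm, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) fits[[nm]] <- fit
  }
  if (!length(fits)) stop("no contrast could be fitted")

  # one (d0, s0_sq) per replicate structure, pooled across its contrasts;
  # a noise-free matrix has no usable variances, handled by the degenerate
  # rule below (zero variance + zero lfc -> unchanged, p = 1; zero variance
  # + nonzero lfc -> certain change, p = 0)
  df_of <- vapply(fits, function(f) f$df[1], numeric(1))
  params_by_df <- list()
  for (d in unique(df_of)) {
    if (!is.null(moderation)) {
      params_by_df[[as.character(d)]] <- moderation
    } else {
      pooled <- unlist(lapply(fits[df_of == d], `[[`, "s2"), use.names = FALSE)
      params_by_df[[as.character(d)]] <- tryCatch(
        estimate_moderation(pooled, d),
        error = function(e) NULL
      )
    }
  }

  tables <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    info <- defs[[nm]]
    par <- params_by_df[[as.character(fit$df[1])]]
    if (is.null(par)) {
      mt <- data.frame(t_mod = ifelse(fit$log2fc == 0, 0,
                                      sign(fit$log2fc) * Inf),
                       df_total = NA_real_,
                       p = ifelse(fit$log2fc == 0, 1, 0),
                       degenerate = TRUE)
    } else {
      mt <- moderated_t(fit$log2fc, fit$s2, fit$df, fit$v, par)
    }
    p <- mt$p
    # degenerate genes (zero posterior variance): no change signal -> p = 1
    p[mt$degenerate & fit$log2fc == 0] <- 1
    adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    adj[ok] <- benjamini_hochberg(p[ok])
    fc <- 2^fit$log2fc
    data.frame(
      gene = fit$gene, contrast = nm, type = info$type,
      tissue = info$tissue, stage = info$stage,
      mean_A = fit$mean_A, mean_B = fit$mean_B,
      log2fc = fit$log2fc, fc = fc,
      t_mod = mt$t_mod, df = mt$df_total, p = p, adj_p = adj,
      call = call_status(fc, adj, fc_threshold, p_threshold),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, tables)
  attr(out, "moderation") <- params_by_df
  attr(out, "thresholds") <- c(fc = fc_threshold, adj_p = p_threshold)
  out
}
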