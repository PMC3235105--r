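#' Pipeline configuration
#'
#' Collects input paths, calling thresholds and the seed for an end-to-end
#' pipeline run. When `matrix_path` is `NULL` the pipeline generates its own
#' synthetic fixture from `sim` (a [sim_config()]), so the whole analysis is
#' runnable without any external data.
#'
#' @param matrix_path,sheet_path Paths to the expression TSV and sample
#'   sheet, or `NULL` to simulate.
#' @param annotation_path Optional GMT path (`NULL`: simulated annotation).
#' @param phenotype_path Optional one-gene-per-line text file for the
#'   false-negative screen (`NULL`: screen skipped unless simulating, in
#'   which case the planted all-stage up-regulated genes are used).
#' @param out_dir Output directory for result tables and the run manifest.
#' @param fc_threshold,p_threshold Differential-expression calling
#'   thresholds (fold change >= 2, adjusted p < 0.001 by default).
#' @param enrich_fold_min,enrich_adjp_max,min_cluster_size Enrichment screen
#'   filters (fold >= 2, adjusted p <= 0.05, clusters of more than 40 genes).
#' @param low_expr_threshold Low-expression flagging cut-off.
#' @param sim A [sim_config()] used when no input paths are given.
#' @param seed Integer seed for the simulated fixture.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(matrix_path = NULL, sheet_path = NULL,
                            annotation_path = NULL, phenotype_path = NULL,
                            out_dir = tempfile("limbtempo_run_"),
                            fc_threshold = 2, p_threshold = 0.001,
                            enrich_fold_min = 2, enrich_adjp_max = 0.05,
                            min_cluster_size = 41, low_expr_threshold = 5,
                            sim = NULL, seed = 1L) {
  thresholds <- c(fc_threshold, p_threshold, enrich_fold_min,
                  enrich_adjp_max, min_cluster_size, low_expr_threshold)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop_config("all thresholds must be positive and finite")
  }
  if (fc_threshold <= 1) stop_config("fc_threshold must exceed 1")
  if (xor(is.null(matrix_path), is.null(sheet_path))) {
    stop_config("matrix_path and sheet_path must be given together")
  }
  for (p in c(matrix_path, sheet_path, annotation_path, phenotype_path)) {
    if (!is.null(p) && !file.exists(p)) stop_config("input file not found: ", p)
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(inherits(sim, "sim_config"))
  structure(list(
    matrix_path = matrix_path, sheet_path = sheet_path,
    annotation_path = annotation_path, phenotype_path = phenotype_path,
    out_dir = out_dir,
    fc_threshold = fc_threshold, p_threshold = p_threshold,
    enrich_fold_min = enrich_fold_min, enrich_adjp_max = enrich_adjp_max,
    min_cluster_size = min_cluster_size,
    low_expr_threshold = low_expr_threshold,
    sim = sim, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains every stage on the configured inputs (or on a freshly simulated
#' fixture): differential expression for all standard contrasts, temporal
#' profile assignment, stage-specific and consecutive-stage-exclusive sets,
#' limb-identity calls, per-cluster enrichment, and the diagnostics
#' (z-normalized group profiles, false-negative screen, low-expression
#' flags). All result tables are written as TSV under `out_dir` together
#' with a machine-readable JSON run manifest (inputs, thresholds, seed,
#' package and R versions) sufficient to reproduce the run.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`de`, `profiles`,
#'   `identity`, `enrichment`, `diagnostics`, ...) and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }

  simulated <- is.null(config$matrix_path)
  truth <- NULL
  if (simulated) {
    design <- build_design(config$sim)
    truth <- simulate_truth(config$sim)
    mat <- simulate_expression(truth, design, config$sim)
    sheet <- design
    ann <- simulate_annotation(truth, config$sim)
  } else {
    mat <- read_expression_matrix(config$matrix_path)
    sheet <- read_sample_sheet(config$sheet_path)
    ann <- if (!is.null(config$annotation_path)) {
      read_gmt(config$annotation_path, universe = rownames(mat))
    } else {
      NULL
    }
  }

  de <- run_all_contrasts(mat, sheet, config$fc_threshold, config$p_threshold)
  profiles <- assign_profiles(de, tissue = "forelimb")
  identity <- limb_identity_calls(de)
  enrichment <- if (!is.null(ann)) {
    enrich_profiles(profiles, ann, config$min_cluster_size,
                    config$enrich_fold_min, config$enrich_adjp_max)
  } else {
    NULL
  }

  z <- z_normalize(mat)
  zprofiles <- group_mean_profiles(z, sheet)
  low_expr <- low_expression_flags(mat, sheet, config$low_expr_threshold)
  phenotype <- NULL
  if (!is.null(config$phenotype_path)) {
    phenotype <- readLines(config$phenotype_path)
    phenotype <- phenotype[nzchar(phenotype)]
  } else if (simulated) {
    phenotype <- truth$gene[truth$fl_pattern == strrep("1", length(config$sim$stages))]
  }
  fn_report <- if (length(phenotype)) {
    false_negative_report(de, mat, sheet, phenotype)
  } else {
    NULL
  }

  paths <- c(
    de = file.path(config$out_dir, "de_table.tsv"),
    profiles = file.path(config$out_dir, "profile_assignments.tsv"),
    identity = file.path(config$out_dir, "identity_calls.tsv"),
    low_expression = file.path(config$out_dir, "low_expression_flags.tsv")
  )
  write_result_table(de, paths[["de"]])
  write_result_table(profiles, paths[["profiles"]])
  write_result_table(identity, paths[["identity"]])
  write_result_table(data.frame(gene = low_expr), paths[["low_expression"]])
  if (!is.null(enrichment)) {
    paths[["enrichment"]] <- file.path(config$out_dir, "enrichment.tsv")
    write_result_table(enrichment, paths[["enrichment"]])
  }

  manifest <- list(
    package = "limbtempo",
    version = as.character(packageVersion("limbtempo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    simulated = simulated,
    inputs = list(matrix = config$matrix_path, sheet = config$sheet_path,
                  annotation = config$annotation_path,
                  phenotype = config$phenotype_path),
    thresholds = list(fc = config$fc_threshold, adj_p = config$p_threshold,
                      enrich_fold = config$enrich_fold_min,
                      enrich_adj_p = config$enrich_adjp_max,
                      min_cluster_size = config$min_cluster_size,
                      low_expression = config$low_expr_threshold),
    seed = config$seed,
    n_genes = nrow(mat), n_arrays = ncol(mat),
    outputs = as.list(paths)
  )
  paths[["manifest"]] <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(
    matrix = mat, sheet = sheet, truth = truth, annotation = ann,
    de = de, profiles = profiles, identity = identity,
    enrichment = enrichment,
    diagnostics = list(z_group_means = zprofiles, low_expression = low_expr,
                       false_negative = fn_report),
    paths = paths
  ))
}
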