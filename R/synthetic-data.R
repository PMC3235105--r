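#' Simulation configuration for the limb time-course design
#'
#' Bundles and validates all parameters of the synthetic-data generator, which
#' emulates the study design of the limb time course: forelimb, hindlimb and
#' whole-embryo arrays at five stages, with hindlimb sampling starting one
#' stage late, log2 intensities spanning roughly 2.4 to 14.6 with median 6.1,
#' planted temporal up-regulation profiles, planted limb-identity genes, and
#' planted enriched annotation categories.
#'
#' @param n_genes Number of genes on the simulated array. The default matches
#'   the effective gene universe of a mouse whole-genome expression array
#'   after collapsing probe sets to genes.
#' @param stages Ordered character vector of developmental stages.
#' @param limb_reps Biological replicates per limb tissue and stage (>= 2).
#' @param we_reps Whole-embryo control replicates per stage (>= 2).
#' @param hl_start_stage First stage with hindlimb samples; must be in
#'   `stages` and must not be the first stage.
#' @param baseline_range Length-2 numeric, the log2 intensity range to which
#'   baselines are clipped.
#' @param baseline_median Target median of the baseline distribution (log2).
#' @param baseline_sdlog Log-scale spread of the shifted log-normal baseline
#'   distribution (see Details).
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise on
#'   the log2 scale.
#' @param effect_log2fc Planted log2 fold change for "up" gene/stage
#'   combinations; the default 2 corresponds to a 4-fold change.
#' @param frac_profiled Fraction of genes given a non-null temporal profile;
#'   must lie in (0, 1].
#' @param n_fl_identity,n_hl_identity Numbers of planted forelimb- and
#'   hindlimb-identity genes (up in one limb only, never in the other).
#' @param n_categories Number of annotation categories to simulate.
#' @param category_size_range Length-2 integer range of category sizes.
#' @param n_planted_categories Number of categories over-sampled from a
#'   planted profile cluster.
#' @param planted_enrichment_fold Target fold enrichment of the planted
#'   categories in their cluster; 1 means no planting (random composition).
#' @param probes_per_gene Probes per gene when probe-level output is requested
#'   from [simulate_expression()].
#' @param drop_arrays Character vector of array ids removed from the design
#'   (e.g. to reproduce a 52-array study from the full 55-array grid).
#' @param seed Integer master seed; all simulation randomness derives from it.
#'
#' @details
#' Baselines are drawn as `lower + LogNormal(log(median - lower), sdlog)` and
#' clipped to `baseline_range`. Clipping preserves the median, so the
#' population of baselines has the configured median and range by
#' construction; the spread parameter controls how closely the extremes of a
#' realistic-sized gene set approach the range limits.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [build_design()], [simulate_truth()], [simulate_expression()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
#' nrow(build_design(cfg))
sim_config <- function(n_genes = 19040,
                       stages = limb_stages(),
                       limb_reps = 5,
                       we_reps = 2,
                       hl_start_stage = "E10.5",
                       baseline_range = c(2.4, 14.6),
                       baseline_median = 6.1,
                       baseline_sdlog = 0.8,
                       noise_sd = 0.25,
                       effect_log2fc = 2,
                       frac_profiled = 0.15,
                       n_fl_identity = 40,
                       n_hl_identity = 20,
                       n_categories = 50,
                       category_size_range = c(10, 200),
                       n_planted_categories = 3,
                       planted_enrichment_fold = 10,
                       probes_per_gene = 11,
                       drop_arrays = character(),
                       seed = 1L) {
  if (n_genes < 1) stop_config("n_genes must be positive")
  if (length(stages) < 2 || anyDuplicated(stages)) {
    stop_config("stages must be >= 2 distinct ordered labels")
  }
  if (limb_reps < 2 || we_reps < 2) {
    stop_config("limb_reps and we_reps must be >= 2: variance estimation requires replication")
  }
  if (!hl_start_stage %in% stages || hl_start_stage == stages[1]) {
    stop_config("hl_start_stage must be a stage later than the first stage")
  }
  if (length(baseline_range) != 2 || diff(baseline_range) <= 0) {
    stop_config("baseline_range must be an increasing length-2 interval")
  }
  if (baseline_median <= baseline_range[1] || baseline_median >= baseline_range[2]) {
    stop_config("baseline_median must lie strictly inside baseline_range")
  }
  if (frac_profiled <= 0 || frac_profiled > 1) {
    stop_config("frac_profiled must lie in (0, 1]")
  }
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (length(category_size_range) != 2 || category_size_range[1] > category_size_range[2] ||
      category_size_range[1] < 1) {
    stop_config("category_size_range must be a non-decreasing positive interval")
  }
  if (category_size_range[2] > n_genes) {
    stop_config("category sizes cannot exceed the gene universe (n_genes)")
  }
  if (planted_enrichment_fold < 1) stop_config("planted_enrichment_fold must be >= 1")
  if (n_planted_categories > n_categories) {
    stop_config("n_planted_categories cannot exceed n_categories")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), stages = stages,
    limb_reps = as.integer(limb_reps), we_reps = as.integer(we_reps),
    hl_start_stage = hl_start_stage,
    baseline_range = baseline_range, baseline_median = baseline_median,
    baseline_sdlog = baseline_sdlog, noise_sd = noise_sd,
    effect_log2fc = effect_log2fc, frac_profiled = frac_profiled,
    n_fl_identity = as.integer(n_fl_identity),
    n_hl_identity = as.integer(n_hl_identity),
    n_categories = as.integer(n_categories),
    category_size_range = as.integer(category_size_range),
    n_planted_categories = as.integer(n_planted_categories),
    planted_enrichment_fold = planted_enrichment_fold,
    probes_per_gene = as.integer(probes_per_gene),
    drop_arrays = drop_arrays, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Build the array design (sample sheet) for a simulation configuration
#'
#' Lays out one row per array: forelimb and whole-embryo samples at every
#' stage, hindlimb samples only from `hl_start_stage` onward. With the default
#' five limb replicates and two whole-embryo replicates this yields a 55-array
#' grid (25 FL + 20 HL + 10 WE); an explicit `drop_arrays` list in the
#' configuration removes named arrays, e.g. to mimic a 52-array study.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `array_id`, `tissue`, `stage`,
#'   `replicate`; array ids are unique.
#' @export
#' @examples
#' nrow(build_design(sim_config()))  # 55
build_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stages <- config$stages
  hl_stages <- stages[seq(match(config$hl_start_stage, stages), length(stages))]
  rows <- list()
  add <- function(tissue, stage, reps) {
    data.frame(
      array_id = sprintf("%s_%s_r%d", tissue_code[[tissue]], stage, seq_len(reps)),
      tissue = tissue, stage = stage, replicate = seq_len(reps),
      stringsAsFactors = FALSE
    )
  }
  for (s in stages) {
    rows[[length(rows) + 1L]] <- add("forelimb", s, config$limb_reps)
    if (s %in% hl_stages) rows[[length(rows) + 1L]] <- add("hindlimb", s, config$limb_reps)
    rows[[length(rows) + 1L]] <- add("whole_embryo", s, config$we_reps)
  }
  sheet <- do.call(rbind, rows)
  if (length(config$drop_arrays)) {
    missing <- setdiff(config$drop_arrays, sheet$array_id)
    if (length(missing)) {
      stop_config("drop_arrays not in design: ", paste(missing, collapse = ", "))
    }
    sheet <- sheet[!sheet$array_id %in% config$drop_arrays, , drop = FALSE]
  }
  rownames(sheet) <- NULL
  stopifnot(!anyDuplicated(sheet$array_id))
  sheet
}

# Observed cluster sizes for the 20 temporal profiles seen in the forelimb
# time course, used as default sampling weights for planted patterns; the 11
# unobserved profiles get a small uniform mass. Bit order is E9.5..E13.5,
# "1" = up-regulated versus the time-matched whole-embryo control.
#' @noRd
default_pattern_weights <- function() {
  w <- c(
    # early: contiguous runs starting at E9.5
    "11111" = 44, "11110" = 68, "11100" = 68, "11000" = 67,
    # peak: internal contiguous runs
    "01100" = 491, "01110" = 401, "00110" = 151,
    # late: contiguous runs ending at E13.5
    "01111" = 475, "00111" = 73, "00011" = 77,
    # stage-specific
    "10000" = 184, "01000" = 190, "00100" = 405, "00010" = 159, "00001" = 183,
    # oscillating
    "10100" = 22, "01001" = 20, "01010" = 51, "01011" = 29, "11101" = 29
  )
  all_patterns <- all_pattern_strings()
  out <- setNames(rep(2, length(all_patterns)), all_patterns)
  out[names(w)] <- w
  out
}

#' @noRd
all_pattern_strings <- function(n_stages = 5L) {
  ids <- seq_len(2^n_stages - 1L)
  vapply(ids, function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(n_stages)]), collapse = "")
  }, character(1))
}

#' Simulate the ground-truth table for a synthetic limb time course
#'
#' Assigns a fraction `frac_profiled` of genes (independent Bernoulli draws)
#' one of the 31 non-empty temporal up-regulation patterns, sampled with
#' weights proportional to the cluster sizes observed in the forelimb time
#' course for the 20 observed patterns and a small mass on the remainder.
#' Separately, disjoint sets of null genes are planted as forelimb-identity
#' (up in the forelimb at every stage, never up in the hindlimb) and
#' hindlimb-identity genes, which by construction satisfy the delay-adjusted
#' identity rules. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @param pattern_weights Optional named numeric vector of sampling weights
#'   over the 31 pattern bitstrings; defaults to the observed-cluster weights.
#' @return A data.frame (class `"truth_table"`) with one row per gene:
#'   `gene`, `fl_pattern` and `hl_pattern` (5-character bitstrings of planted
#'   up-states per stage, `"00000"` for null), `class_id` (1-31 for profiled
#'   genes, NA otherwise), `identity` (`"none"`, `"forelimb"`, `"hindlimb"`),
#'   `true_log2fc`.
#' @export
simulate_truth <- function(config, pattern_weights = default_pattern_weights()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$frac_profiled <= 0) stop_config("frac_profiled must be > 0 to plant any signal")
  patterns <- all_pattern_strings(length(config$stages))
  if (length(config$stages) == 5L) {
    stopifnot(all(names(pattern_weights) %in% patterns))
    w <- pattern_weights[patterns]
    w[is.na(w)] <- 0
  } else {
    w <- rep(1, length(patterns))
  }
  n <- config$n_genes
  genes <- gene_ids(n)
  with_seed(sub_seed(config$seed, 1L), {
    profiled <- runif(n) < config$frac_profiled
    pat <- rep(strrep("0", nchar(patterns[1])), n)
    pat[profiled] <- sample(patterns, sum(profiled), replace = TRUE, prob = w)
    null_genes <- which(!profiled)
    n_id <- config$n_fl_identity + config$n_hl_identity
    if (n_id > length(null_genes)) {
      stop_config("not enough null genes to plant identity labels")
    }
    id_idx <- null_genes[sample.int(length(null_genes), n_id)]
  })
  fl_idx <- id_idx[seq_len(config$n_fl_identity)]
  hl_idx <- setdiff(id_idx, fl_idx)
  identity <- rep("none", n)
  identity[fl_idx] <- "forelimb"
  identity[hl_idx] <- "hindlimb"

  fl_pattern <- pat
  hl_pattern <- pat
  all_up <- strrep("1", length(config$stages))
  none_up <- strrep("0", length(config$stages))
  # hindlimb arrays only exist from hl_start_stage, so bits before it are inert
  fl_pattern[fl_idx] <- all_up
  hl_pattern[fl_idx] <- none_up
  fl_pattern[hl_idx] <- none_up
  hl_pattern[hl_idx] <- all_up

  truth <- data.frame(
    gene = genes,
    fl_pattern = fl_pattern,
    hl_pattern = hl_pattern,
    class_id = ifelse(fl_pattern == none_up, NA_integer_, strtoi(fl_pattern, base = 2L)),
    identity = identity,
    true_log2fc = ifelse(fl_pattern == none_up & hl_pattern == none_up,
                         0, config$effect_log2fc),
    stringsAsFactors = FALSE
  )
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' @noRd
pattern_bits <- function(pattern_strings) {
  t(vapply(strsplit(pattern_strings, ""),
           function(b) as.integer(b) == 1L,
           logical(nchar(pattern_strings[1]))))
}

#' Simulate a log2 expression matrix (optionally probe-level) from truth
#'
#' Each gene receives a baseline drawn from a shifted log-normal distribution
#' clipped to the configured range and centred on the configured median (6.1
#' by default, matching arrays whose log2 values span 2.4 to 14.6). Limb
#' arrays at stages where the gene's planted pattern is "up" get
#' `baseline + true_log2fc`; whole-embryo arrays always sit at baseline.
#' I.i.d. Gaussian noise with `noise_sd` is added on the log2 scale. Noise is
#' drawn gene-by-gene from a dedicated stream, so enlarging the gene set does
#' not perturb the noise of existing genes.
#'
#' @param truth A [simulate_truth()] table.
#' @param design A [build_design()] sample sheet.
#' @param config The [sim_config()] both were generated from.
#' @param probe_level If `TRUE`, return probe-level intensities
#'   (`probes_per_gene` probes per gene with fixed additive probe affinities)
#'   for exercising summarization, plus the probe-to-gene map.
#' @return A genes x arrays numeric matrix of log2 intensities, or if
#'   `probe_level = TRUE` a list with elements `probes` (probe x array
#'   matrix) and `probe_map` (data.frame `probe`, `gene`).
#' @export
simulate_expression <- function(truth, design, config, probe_level = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  if (!setequal(truth$gene, gene_ids(config$n_genes))) {
    stop_config("truth table gene set does not match the configuration")
  }
  n <- nrow(truth)
  n_arr <- nrow(design)
  lo <- config$baseline_range[1]; hi <- config$baseline_range[2]
  with_seed(sub_seed(config$seed, 2L), {
    baseline <- lo + rlnorm(n, meanlog = log(config$baseline_median - lo),
                            sdlog = config$baseline_sdlog)
    baseline <- pmin(baseline, hi)
  })

  fl_up <- pattern_bits(truth$fl_pattern)
  hl_up <- pattern_bits(truth$hl_pattern)
  stage_idx <- match(design$stage, config$stages)
  effect <- matrix(0, n, n_arr)
  is_fl <- design$tissue == "forelimb"
  is_hl <- design$tissue == "hindlimb"
  effect[, is_fl] <- config$effect_log2fc * fl_up[, stage_idx[is_fl], drop = FALSE]
  effect[, is_hl] <- config$effect_log2fc * hl_up[, stage_idx[is_hl], drop = FALSE]

  signal <- baseline + effect
  dimnames(signal) <- list(truth$gene, design$array_id)

  if (!probe_level) {
    with_seed(sub_seed(config$seed, 3L), {
      for (g in seq_len(n)) {
        signal[g, ] <- signal[g, ] + rnorm(n_arr, sd = config$noise_sd)
      }
    })
    return(signal)
  }

  p <- config$probes_per_gene
  probe_map <- data.frame(
    probe = sprintf("%s_p%02d", rep(truth$gene, each = p), rep(seq_len(p), n)),
    gene = rep(truth$gene, each = p),
    stringsAsFactors = FALSE
  )
  probes <- matrix(0, n * p, n_arr,
                   dimnames = list(probe_map$probe, design$array_id))
  with_seed(sub_seed(config$seed, 3L), {
    for (g in seq_len(n)) {
      affinity <- rnorm(p, sd = 0.7)
      rows <- (g - 1L) * p + seq_len(p)
      probes[rows, ] <- matrix(signal[g, ], p, n_arr, byrow = TRUE) + affinity +
        rnorm(p * n_arr, sd = config$noise_sd)
    }
  })
  list(probes = probes, probe_map = probe_map)
}

#' Simulate a gene annotation with planted enriched categories
#'
#' Draws `n_categories` gene sets with sizes uniform in
#' `category_size_range`. The first `n_planted_categories` categories are
#' over-sampled from the genes sharing the most common planted temporal
#' pattern so that the category's expected fold enrichment in that cluster is
#' approximately `planted_enrichment_fold`; with fold 1 the composition is a
#' plain random draw from the universe.
#'
#' @param truth A [simulate_truth()] table.
#' @param config The matching [sim_config()].
#' @return An [annotation_set()] whose universe is all simulated genes, with
#'   attribute `"planted"` naming the planted categories and
#'   `"planted_cluster"` the pattern bitstring of the target cluster.
#' @export
simulate_annotation <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  universe <- truth$gene
  profiled <- truth$fl_pattern[truth$fl_pattern != strrep("0", nchar(truth$fl_pattern[1]))]
  target_pattern <- names(sort(table(profiled), decreasing = TRUE))[1]
  cluster <- truth$gene[truth$fl_pattern == target_pattern]
  N <- length(universe); m <- length(cluster)
  with_seed(sub_seed(config$seed, 4L), {
    sizes <- sample(seq(config$category_size_range[1], config$category_size_range[2]),
                    config$n_categories, replace = TRUE)
    sets <- vector("list", config$n_categories)
    names(sets) <- sprintf("CAT%04d", seq_len(config$n_categories))
    for (i in seq_len(config$n_categories)) {
      K <- sizes[i]
      if (K > N) stop_config("category size exceeds the gene universe")
      if (i <= config$n_planted_categories && config$planted_enrichment_fold > 1 && m > 0) {
        k <- min(round(config$planted_enrichment_fold * K * m / N), K, m)
        inside <- sample(cluster, k)
        outside <- sample(setdiff(universe, cluster), K - k)
        sets[[i]] <- sort(c(inside, outside))
      } else {
        sets[[i]] <- sort(sample(universe, K))
      }
    }
  })
  ann <- annotation_set(sets,
                        description = setNames(rep("synthetic category", length(sets)),
                                               names(sets)),
                        universe = universe)
  attr(ann, "planted") <- names(sets)[seq_len(config$n_planted_categories)]
  attr(ann, "planted_cluster") <- target_pattern
  ann
}

#' Write a complete synthetic fixture to disk
#'
#' Writes the expression matrix, sample sheet and truth table as TSV and the
#' annotation as GMT; all files round-trip losslessly through the package's
#' readers ([read_expression_matrix()], [read_sample_sheet()], [read_gmt()],
#' [read_truth()]).
#'
#' @param matrix Genes x arrays expression matrix.
#' @param sheet Sample sheet data.frame.
#' @param annotation An [annotation_set()].
#' @param truth A [simulate_truth()] table.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixture <- function(matrix, sheet, annotation, truth, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    matrix = file.path(out_dir, "expression.tsv"),
    sheet = file.path(out_dir, "samples.tsv"),
    annotation = file.path(out_dir, "annotation.gmt"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_expression_matrix(matrix, paths[["matrix"]])
  write_sample_sheet(sheet, paths[["sheet"]])
  write_gmt(annotation, paths[["annotation"]])
  write_truth(truth, paths[["truth"]])
  invisible(paths)
}
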