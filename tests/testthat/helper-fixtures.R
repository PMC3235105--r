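# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

tiny_config <- function(n_genes = 600, noise_sd = 0.1, seed = 101L,
                        n_fl_identity = 15, n_hl_identity = 8,
                        n_categories = 20, category_size_range = c(5, 60),
                        ...) {
  sim_config(n_genes = n_genes, noise_sd = noise_sd, seed = seed,
             n_fl_identity = n_fl_identity, n_hl_identity = n_hl_identity,
             n_categories = n_categories,
             category_size_range = category_size_range, ...)
}

tiny_fixture <- function(config = tiny_config()) {
  design <- build_design(config)
  truth <- simulate_truth(config)
  mat <- simulate_expression(truth, design, config)
  list(config = config, design = design, truth = truth, matrix = mat)
}

# Minimal hand-crafted DE table for identity/clustering logic tests:
# `calls` is a named list tissue -> stage -> named character vector of calls
# per gene (genes missing from a stage are "unchanged").
make_de <- function(genes, calls) {
  rows <- list()
  for (tissue in names(calls)) {
    for (stage in names(calls[[tissue]])) {
      cl <- rep("unchanged", length(genes))
      names(cl) <- genes
      given <- calls[[tissue]][[stage]]
      if (length(given)) cl[names(given)] <- given
      code <- if (tissue == "forelimb") "FL" else "HL"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes, contrast = paste0(code, "_", stage),
        type = "limb_vs_we", tissue = tissue, stage = stage,
        mean_A = 0, mean_B = 0, log2fc = ifelse(cl == "up", 2, 0),
        fc = ifelse(cl == "up", 4, 1), t_mod = 0, df = 10,
        p = ifelse(cl == "unchanged", 1, 1e-6),
        adj_p = ifelse(cl == "unchanged", 1, 1e-5),
        call = unname(cl), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# A two-group sample sheet for single-contrast statistics tests.
two_group_sheet <- function(n_a, n_b, tissue_a = "forelimb",
                            tissue_b = "whole_embryo", stage = "E10.5") {
  data.frame(
    array_id = c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b))),
    tissue = c(rep(tissue_a, n_a), rep(tissue_b, n_b)),
    stage = stage,
    replicate = c(seq_len(n_a), seq_len(n_b)),
    stringsAsFactors = FALSE
  )
}
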