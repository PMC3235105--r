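test_that("z-normalization centers and scales each gene across arrays", {
  m <- rbind(g1 = c(1, 3), g2 = c(10, 30))
  colnames(m) <- c("a1", "a2")
  z <- z_normalize(m)
  # population sd: a two-array gene maps to (-1, +1)
  expect_equal(unname(z["g1", ]), c(-1, 1))
  # sample-sd convention on request
  zs <- z_normalize(m, sd_type = "sample")
  expect_equal(unname(zs["g1", ]), c(-1, 1) / sqrt(2))

  set.seed(4)
  big <- matrix(rnorm(500, mean = 6), 25, 20,
                dimnames = list(sprintf("g%02d", 1:25), sprintf("a%02d", 1:20)))
  zb <- z_normalize(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(zb^2) / ncol(zb)) - 1)), 1e-9)

  # affine transforms of a gene leave its z-scores unchanged
  expect_equal(z_normalize(3 * big + 7), zb)

  # idempotence
  expect_equal(z_normalize(zb), zb, tolerance = 1e-12)

  # constant genes are dropped; all-constant input is an error
  with_const <- rbind(big, flat = rep(5, 20))
  expect_message(zc <- z_normalize(with_const), "constant gene")
  expect_false("flat" %in% rownames(zc))
  expect_equal(attr(zc, "dropped"), "flat")
  expect_error(z_normalize(rbind(a = rep(1, 4), b = rep(2, 4))), "constant")
})

test_that("group-mean z profiles expose planted oscillation", {
  cfg <- tiny_config(n_genes = 300, noise_sd = 0.05, seed = 81)
  design <- build_design(cfg)
  truth <- simulate_truth(cfg)
  # plant an oscillating profile explicitly: up at E10.5 and E12.5 only
  osc <- truth$gene[truth$fl_pattern == "00000" & truth$identity == "none"][1]
  truth$fl_pattern[truth$gene == osc] <- "01010"
  truth$hl_pattern[truth$gene == osc] <- "01010"
  fx <- list(design = design, truth = truth,
             matrix = simulate_expression(truth, design, cfg))
  z <- z_normalize(fx$matrix)
  gm <- group_mean_profiles(z, fx$design)
  fl_cols <- paste0("forelimb.", limb_stages())
  prof <- gm[osc, fl_cols]
  # the two planted stages dominate the forelimb profile
  expect_setequal(names(sort(prof, decreasing = TRUE))[1:2],
                  c("forelimb.E10.5", "forelimb.E12.5"))
  # whole-embryo means sit below the limb means for planted limb genes
  we_cols <- paste0("whole_embryo.", c("E10.5", "E12.5"))
  expect_true(all(gm[osc, we_cols] < prof[c("forelimb.E10.5", "forelimb.E12.5")]))

  # all-equal z rows give equal group means; group means recombine to 0
  zflat <- matrix(0.5, 2, ncol(z), dimnames = list(c("x", "y"), colnames(z)))
  gflat <- group_mean_profiles(zflat, fx$design)
  expect_true(all(gflat == 0.5))
  sizes <- table(paste(fx$design$tissue, fx$design$stage, sep = "."))
  weights <- as.numeric(sizes[colnames(gm)]) / sum(sizes)
  expect_lt(max(abs(gm %*% weights)), 1e-9)
})

test_that("Wilcoxon rank-sum handles the textbook cases", {
  # identical samples: no evidence at all
  expect_equal(wilcoxon_rank_sum(1:6, 1:6)$p.value, 1)
  # x=(1,2), y=(3,4): one-sided 1/6, two-sided 1/3 by enumeration of C(4,2)
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 3)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("Wilcoxon agrees with enumeration and reference implementations", {
  set.seed(19)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:10, nx, replace = TRUE)  # ties likely
    y <- sample(1:10, ny, replace = TRUE)
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$p.value, wilcox_oracle(x, y), tolerance = 1e-12)
    # two-sided symmetry under swapping the samples
    expect_equal(wilcoxon_rank_sum(y, x)$p.value, mine$p.value, tolerance = 1e-12)
  }

  # tie-free exact case against the reference distribution
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6)
    mine <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }

  # exact and normal approximation agree closely at moderate sizes
  set.seed(20)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- wilcoxon_rank_sum(x, y, exact_max_n = 12)$p.value
    normal <- wilcoxon_rank_sum(x, y, exact_max_n = 0)$p.value
    expect_lt(abs(exact - normal), 0.02)
  }

  # large-sample normal path against the reference implementation
  set.seed(21)
  x <- rnorm(30); y <- rnorm(25) + 0.5
  mine <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$method, "normal")
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("the false-negative screen reproduces the low-expression signature", {
  cfg <- tiny_config(n_genes = 800, noise_sd = 0.15, seed = 91)
  fx <- tiny_fixture(cfg)

  # positive control: a phenotype list of planted up-regulated genes (every
  # profiled gene is up in at least one comparison)
  up_list <- fx$truth$gene[fx$truth$fl_pattern != "00000" &
                             fx$truth$identity == "none"]
  de <- run_all_contrasts(fx$matrix, fx$design)
  pos <- false_negative_report(de, fx$matrix, fx$design, up_list)
  expect_equal(pos$fraction_up, 1.0)
  # with no missed genes the missed-versus-recovered comparisons are undefined
  expect_true(all(is.na(pos$wilcoxon$p[pos$wilcoxon$comparison ==
                                         "not_up_vs_up_phenotype"])))

  # designed fixture: half the phenotype genes have their limb expression
  # suppressed below the detectable effect, whole-embryo expression untouched
  null_pool <- fx$truth$gene[fx$truth$fl_pattern == "00000" &
                               fx$truth$hl_pattern == "00000"]
  suppressed <- null_pool[1:40]
  mat2 <- fx$matrix
  limb_arrays <- fx$design$array_id[fx$design$tissue %in% c("forelimb", "hindlimb")]
  mat2[suppressed, limb_arrays] <- mat2[suppressed, limb_arrays] - 4
  de2 <- run_all_contrasts(mat2, fx$design)
  phenotype <- c(up_list[1:40], suppressed)
  stopifnot(!anyNA(phenotype))
  rep2 <- false_negative_report(de2, mat2, fx$design, phenotype)
  expect_equal(rep2$n_on_array, 80L)
  expect_equal(rep2$n_up, 40L)
  wl <- rep2$wilcoxon
  p_limb <- wl$p[wl$comparison == "not_up_vs_up_phenotype" & wl$compartment == "limb"]
  p_we <- wl$p[wl$comparison == "not_up_vs_up_phenotype" &
                 wl$compartment == "whole_embryo"]
  expect_lt(p_limb, 0.001)  # missed genes sit lower in the limb
  expect_gt(p_we, 0.05)     # but look the same in the whole embryo

  expect_error(false_negative_report(de, fx$matrix, fx$design, c("no_such_gene")),
               "disjoint")
})

test_that("low-expression flagging requires all stages below threshold", {
  cfg <- tiny_config(n_genes = 100, noise_sd = 0, seed = 96)
  fx <- tiny_fixture(cfg)
  mat <- fx$matrix
  low_all <- rownames(mat)[1]
  low_partial <- rownames(mat)[2]
  mat[low_all, ] <- 4.9
  mat[low_partial, ] <- 4.9
  e12_limb <- fx$design$array_id[fx$design$tissue %in% c("forelimb", "hindlimb") &
                                   fx$design$stage == "E12.5"]
  mat[low_partial, e12_limb] <- 5.1

  flags <- low_expression_flags(mat, fx$design, threshold = 5)
  expect_true(low_all %in% flags)
  expect_false(low_partial %in% flags)

  # the expression floor sits near 2.4, so threshold 0 flags nothing
  expect_length(low_expression_flags(fx$matrix, fx$design, threshold = 0), 0)

  # a stage without limb samples is an error
  no_e135 <- fx$design[!(fx$design$stage == "E13.5" &
                           fx$design$tissue %in% c("forelimb", "hindlimb")), ]
  expect_error(low_expression_flags(mat, no_e135, threshold = 5),
               "no limb samples")
})
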