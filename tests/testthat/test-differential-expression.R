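test_that("two-group gene statistics match hand computations", {
  sheet <- two_group_sheet(2, 2)
  m <- rbind(g1 = c(3, 5, 1, 1), g2 = c(2, 2, 7, 7))
  colnames(m) <- sheet$array_id
  def <- contrast_def("c", "forelimb", "E10.5", "whole_embryo", "E10.5")
  fit <- fit_gene_stats(m, sheet, def)

  # A = {3,5}, B = {1,1}: lfc = 3, pooled s2 = (2 + 0)/2 = 1, df = 2, v = 1
  expect_equal(fit$log2fc[1], 3)
  expect_equal(fit$s2[1], 1)
  expect_equal(fit$df[1], 2L)
  expect_equal(fit$v[1], 1)

  # constant groups: zero variance, lfc = difference of constants
  expect_equal(fit$s2[2], 0)
  expect_equal(fit$log2fc[2], -5)

  # permuting arrays within a group changes nothing
  m2 <- m[, c(2, 1, 4, 3)]
  fit2 <- fit_gene_stats(m2, sheet, def)
  expect_equal(fit2, fit)

  # group with < 2 arrays is an error
  expect_error(fit_gene_stats(m[, -1], sheet, def), ">= 2 arrays")
})

test_that("moderation estimation handles zero dispersion and recovers parameters", {
  # all variances equal: infinite prior df, prior variance = the common value
  par <- estimate_moderation(rep(0.05, 100), 5)
  expect_equal(par$d0, Inf)
  expect_equal(par$s0_sq, 0.05)

  # parameter recovery from the generative model (scaled inverse-chi-square
  # prior, chi-square sampling scatter)
  set.seed(99)
  d0 <- 4; s0 <- 0.05; n <- 5000; dg <- 5
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  est <- estimate_moderation(s2, dg)
  expect_gte(est$d0, 2.5)
  expect_lte(est$d0, 6.5)
  expect_lt(abs(est$s0_sq - s0) / s0, 0.3)

  expect_error(estimate_moderation(rep(0, 50), 5), "zero or unusable")
  expect_error(estimate_moderation(c(0.1, 0.2), 5), ">= 10 genes")
})

test_that("moderation estimation agrees with the reference empirical-Bayes fit", {
  set.seed(31)
  s2 <- 0.05 * rchisq(2000, 6) / 6 * exp(rnorm(2000, sd = 0.4))
  mine <- estimate_moderation(s2, 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(mine$d0, ref$df2, tolerance = 1e-8)
  expect_equal(mine$s0_sq, ref$scale, tolerance = 1e-8)
})

test_that("the trigamma inverse matches a grid-search oracle", {
  set.seed(3)
  rhs <- exp(runif(20, log(0.01), log(5)))
  for (x in rhs) {
    mine <- limbtempo:::trigamma_inverse(x)
    expect_equal(trigamma(mine), x, tolerance = 1e-9)
    expect_equal(mine, trigamma_inverse_oracle(x), tolerance = 1e-6)
  }
})

test_that("moderated t reduces to known limits and matches the formula oracle", {
  # fixed-input formula oracle
  lfc <- 1; s2 <- 0.25; dg <- 5; v <- 0.7; d0 <- 3; s0 <- 0.09
  got <- moderated_t(lfc, s2, dg, v, moderation_params(d0, s0))
  s_post <- (d0 * s0 + dg * s2) / (d0 + dg)
  t_exp <- lfc / sqrt(s_post * v)
  expect_equal(got$t_mod, t_exp, tolerance = 1e-12)
  expect_equal(got$df_total, d0 + dg)
  expect_equal(got$p, 2 * pt(-abs(t_exp), d0 + dg), tolerance = 1e-12)

  # d0 = 0: ordinary pooled two-sample t
  plain <- moderated_t(lfc, s2, dg, v, moderation_params(0, 1))
  expect_equal(plain$t_mod, lfc / sqrt(s2 * v), tolerance = 1e-12)
  expect_equal(plain$df_total, dg)

  # d0 = Inf: all genes share the prior variance, t proportional to lfc
  inf <- moderated_t(c(1, 2, 3), c(0.1, 0.5, 0.9), dg, v,
                     moderation_params(Inf, s0))
  expect_equal(inf$t_mod, c(1, 2, 3) / sqrt(s0 * v), tolerance = 1e-12)
  expect_true(all(is.infinite(inf$df_total)))

  # zero effect: t = 0, p = 1
  null <- moderated_t(0, s2, dg, v, moderation_params(d0, s0))
  expect_equal(null$t_mod, 0)
  expect_equal(null$p, 1)

  # monotone in |lfc| at fixed variances
  ts <- abs(moderated_t(c(0.1, 0.5, 2, 4), s2, dg, v,
                        moderation_params(d0, s0))$t_mod)
  expect_true(all(diff(ts) > 0))

  # degenerate posterior variance is flagged
  deg <- moderated_t(1, 0, dg, v, moderation_params(0, 1))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("moderated pipeline reproduces the reference eBayes t-statistics", {
  set.seed(7)
  ng <- 300
  m <- matrix(rnorm(ng * 8, sd = 0.3), ng, 8)
  m[1:30, 1:4] <- m[1:30, 1:4] + 1
  rownames(m) <- sprintf("g%03d", seq_len(ng))
  colnames(m) <- sprintf("a%d", 1:8)
  sheet <- two_group_sheet(4, 4)
  sheet$array_id <- colnames(m)

  fit <- fit_gene_stats(m, sheet,
                        contrast_def("c", "forelimb", "E10.5", "whole_embryo", "E10.5"))
  par <- estimate_moderation(fit$s2, fit$df[1])
  mt <- moderated_t(fit$log2fc, fit$s2, fit$df, fit$v, par)

  ref <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 4))))
  expect_equal(mt$t_mod, unname(ref$t[, 2]), tolerance = 1e-10)
  expect_equal(mt$p, unname(ref$p.value[, 2]), tolerance = 1e-10)
})

test_that("Benjamini-Hochberg matches hand values and the brute-force oracle", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (rep in 1:1000) {
    n <- sample(1:8, 1)
    p <- runif(n)
    expect_identical(benjamini_hochberg(p), bh_oracle(p))
  }

  # permutation equivariance
  p <- runif(30)
  perm <- sample(30)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("calling thresholds implement the fold-change and adjusted-p rule", {
  expect_equal(call_status(2.0, 0.0005), "up")
  expect_equal(call_status(1.0, 1e-10), "unchanged")  # fold change 1 = no change
  expect_equal(call_status(0.5, 0.0005), "down")      # reduction by half
  expect_equal(call_status(4, 0.01), "unchanged")     # fails the p threshold
  expect_equal(call_status(1.9, 1e-6), "unchanged")   # fails the fc threshold
  expect_equal(call_status(c(8, 0.1, 1.5), c(1e-5, 1e-5, 1e-5)),
               c("up", "down", "unchanged"))
  expect_error(call_status(-1, 0.5), "positive")
})

test_that("the full contrast set recovers planted genes with controlled errors", {
  cfg <- tiny_config(n_genes = 800, noise_sd = 0.1, seed = 21)
  fx <- tiny_fixture(cfg)
  de <- run_all_contrasts(fx$matrix, fx$design)

  # every planted (gene, stage) with an up state is called up: sensitivity 1
  stages <- cfg$stages
  limb_de <- de[de$type == "limb_vs_we" & de$tissue == "forelimb", ]
  planted <- fx$truth[fx$truth$fl_pattern != "00000", ]
  misses <- 0L
  for (i in seq_len(nrow(planted))) {
    up_stages <- stages[strsplit(planted$fl_pattern[i], "")[[1]] == "1"]
    calls <- limb_de$call[limb_de$gene == planted$gene[i] &
                            limb_de$stage %in% up_stages]
    misses <- misses + sum(calls != "up")
  }
  expect_equal(misses, 0L)

  # up and down are disjoint per contrast by construction of the call
  for (cn in unique(de$contrast)) {
    sub <- de[de$contrast == cn, ]
    expect_length(intersect(sub$gene[sub$call == "up"],
                            sub$gene[sub$call == "down"]), 0)
  }

  # expected standard contrasts: FL x5, HL x4, FLvHL x4
  expect_equal(sum(grepl("^FL_", unique(de$contrast))), 5L)
  expect_equal(sum(grepl("^HL_", unique(de$contrast))), 4L)
  expect_equal(sum(grepl("^FLvHL_", unique(de$contrast))), 4L)

  # fc column is exactly 2^log2fc
  expect_equal(de$fc, 2^de$log2fc)
})

test_that("null data yields up-calls at no more than the nominal rate", {
  cfg <- tiny_config(n_genes = 2000, noise_sd = 0.25, seed = 33)
  design <- build_design(cfg)
  truth <- simulate_truth(cfg)
  # erase all planted signal: a pure-noise null fixture
  truth$fl_pattern <- "00000"
  truth$hl_pattern <- "00000"
  truth$true_log2fc <- 0
  mat <- simulate_expression(truth, design, cfg)
  de <- run_all_contrasts(mat, design)
  expect_lte(mean(de$call == "up"), 0.001)
})
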