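# Proof-of-principle and validation statistics.

test_that("relative_z is the ratio of set to overall mean |z|", {
  tab <- ztab(c("A", "B", "C", "D"), c(3, 1, -1, 1))
  all_set <- gene_set("all", tab$gene)
  expect_equal(relative_z(tab, all_set)$ratio, 1)
  rz <- relative_z(tab, gene_set("a", "A"))
  expect_equal(rz$ratio, 3 / 1.5)
  expect_equal(rz$n_set, 1L)
  expect_error(relative_z(tab, gene_set("x", "NOPE")), "'x'")
})

test_that("relative_z of random gene sets concentrates near 1", {
  set.seed(17)
  tab <- ztab(sprintf("G%04d", 1:2000), rnorm(2000, sd = 1.4))
  ratios <- vapply(1:200, function(i)
    relative_z(tab, gene_set("r", sample(tab$gene, 100)))$ratio,
    numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("enrichment_ttest matches the pooled formula and its edge cases", {
  # identical |z| distributions in and out of the set -> t = 0
  tab0 <- ztab(c("A", "B", "C", "D"), c(1, 2, -1, -2))
  expect_equal(enrichment_ttest(tab0, gene_set("s", c("A", "B")))$t, 0)
  # degenerate pooled variance with separated means -> +Inf
  tab1 <- ztab(c("A", "B", "C", "D", "E", "F"), c(3, -3, 1, 1, -1, -1))
  tt <- enrichment_ttest(tab1, gene_set("s", c("A", "B")))
  expect_equal(tt$t, Inf)
  expect_equal(tt$df, 4L)
  # df is always gene count - 2
  set.seed(23)
  tab <- ztab(sprintf("G%03d", 1:40), rnorm(40))
  expect_equal(enrichment_ttest(tab, gene_set("s", tab$gene[1:7]))$df, 38L)
  expect_error(enrichment_ttest(tab, gene_set("s", tab$gene[1])), ">= 2")
})

test_that("enrichment_ttest agrees with stats::t.test on random instances", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    tab <- ztab(sprintf("G%03d", 1:n), rnorm(n, sd = runif(1, 0.5, 3)))
    set <- gene_set("s", sample(tab$gene, sample(2:(n - 2), 1)))
    mine <- enrichment_ttest(tab, set)
    ref <- stats::t.test(abs(tab$z[tab$gene %in% set$genes]),
                         abs(tab$z[!tab$gene %in% set$genes]),
                         var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("pearson_z_correlation works on the shared-gene intersection", {
  set.seed(31)
  a <- random_ztab(50)
  expect_equal(pearson_z_correlation(a, a)$r, 1)
  neg <- ztab(a$gene, -a$z)
  expect_equal(pearson_z_correlation(a, neg)$r, -1)
  expect_error(pearson_z_correlation(ztab("A", 1), ztab("A", 1)), ">= 3")
  # sampled bivariate normal with true rho = 0.3
  n <- 10000
  z1 <- rnorm(n)
  z2 <- 0.3 * z1 + sqrt(1 - 0.09) * rnorm(n)
  genes <- sprintf("G%05d", 1:n)
  pc <- pearson_z_correlation(ztab(genes, z1), ztab(genes, z2))
  expect_lt(abs(pc$r - 0.3), 0.03)
  expect_equal(pc$n, n)
})

test_that("compare_correlations implements the Fisher r-to-z test", {
  expect_equal(compare_correlations(0.4, 100, 0.4, 250)$z, 0)
  # frozen from an arbitrary-precision evaluation of the formula
  expect_equal(compare_correlations(0.36, 10824, 0.22, 11984)$z,
               11.5541226787822, tolerance = 1e-9)
  expect_equal(compare_correlations(0.1, 50, 0.3, 80)$z,
               -compare_correlations(0.3, 80, 0.1, 50)$z)
  # monotone in r1 for fixed r2, n1, n2
  zz <- vapply(seq(-0.9, 0.9, by = 0.1),
               function(r1) compare_correlations(r1, 60, 0.2, 70)$z,
               numeric(1))
  expect_true(all(diff(zz) > 0))
  expect_error(compare_correlations(1, 10, 0.2, 10), "< 1")
  expect_error(compare_correlations(0.5, 3, 0.2, 10), "> 3")
})

test_that("spearman_rank_validation recovers monotone and null relations", {
  set.seed(37)
  tab <- random_ztab(60)
  lr <- stats::setNames(exp(tab$z), tab$gene)   # strictly increasing in z
  expect_equal(spearman_rank_validation(tab, lr)$rho, 1)
  expect_equal(spearman_rank_validation(tab, -lr)$rho, -1)
  big <- ztab(sprintf("G%04d", 1:1000), rnorm(1000))
  noise <- stats::setNames(rnorm(1000), big$gene)
  sp <- spearman_rank_validation(big, noise)
  expect_lt(abs(sp$rho), 0.1)
  expect_equal(sp$n, 1000L)
  # data.frame input form
  df <- data.frame(gene = tab$gene, log_ratio = unname(lr))
  expect_equal(spearman_rank_validation(tab, df)$rho, 1)
})

test_that("set_mean_z reports signed means for up/down/all", {
  tab <- ztab(c("A", "B"), c(2, -2))
  s <- set_mean_z(tab, gene_set("up", "A"), gene_set("down", "B"))
  expect_equal(s$mean_up, 2)
  expect_equal(s$mean_down, -2)
  expect_equal(s$mean_all, 0)
  allset <- gene_set("all", tab$gene)
  s2 <- set_mean_z(tab, allset, allset)
  expect_equal(s2$mean_up, s2$mean_down)
  expect_equal(s2$mean_up, s2$mean_all)
  expect_error(set_mean_z(tab, gene_set("x", "NOPE"), allset), "intersect")
})

test_that("an external study sharing planted effects separates the set means", {
  tr <- generate_truth(n_genes = 1500, n_effect_per_contrast = 50,
                       n_hubs = 0, seed = 43)
  col <- simulate_study_collection(tr, seed = 44)
  res <- suppressMessages(run_pipeline(list(studies = col)))
  up <- gene_set("up", names(which(tr$effect$metastasis > 0)))
  down <- gene_set("down", names(which(tr$effect$metastasis < 0)))
  s <- set_mean_z(res$level3, up, down)
  expect_gt(s$mean_up, s$mean_all)
  expect_gt(s$mean_all, s$mean_down)
})

test_that("per_gene_ttest matches a textbook implementation", {
  tr <- toy_truth(n_genes = 100, seed = 47)
  em <- generate_expression_matrix(tr, n_case = 6, n_control = 8,
                                   noise_sd = 1, seed = 48)
  res <- per_gene_ttest(em)
  ref_t <- apply(em$values, 1, function(x) {
    unname(stats::t.test(x[em$groups == "case"], x[em$groups == "control"],
                         var.equal = TRUE)$statistic)
  })
  expect_equal(res$t, unname(ref_t), tolerance = 1e-10)
  expect_equal(res$log_ratio,
               unname(rowMeans(em$values[, em$groups == "case"]) -
                      rowMeans(em$values[, em$groups == "control"])),
               tolerance = 1e-12)
  expect_equal(res$direction, ifelse(res$log_ratio >= 0, "up", "down"))
})

test_that("per_gene_ttest handles equal means and zero variance", {
  vals <- rbind(c(1, 2, 3, 1, 2, 3),       # same group means, nonzero var
                c(5, 5, 5, 5, 5, 5))       # zero pooled variance
  rownames(vals) <- c("SAME", "FLAT")
  em <- list(values = vals,
             groups = factor(rep(c("case", "control"), each = 3),
                             levels = c("case", "control")))
  expect_warning(res <- per_gene_ttest(em), "zero pooled variance")
  expect_equal(res$log_ratio, c(0, 0))
  expect_equal(res$p_value[res$gene == "FLAT"], 1)
  expect_gt(res$p_value[res$gene == "SAME"], 0.99)
})

test_that("bonferroni caps m * p at 1 and validates its input", {
  expect_equal(bonferroni(rep(0.01, 10))[1], 0.1)
  expect_equal(bonferroni(rep(0.5, 10))[1], 1)
  expect_equal(bonferroni(0.37), 0.37)
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})
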