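# Signed-Z mathematics: conversion, combination, balancing, contrasts.

test_that("clamp_p keeps interior p and pins the boundaries", {
  expect_equal(clamp_p(0), 1e-15)
  expect_equal(clamp_p(1), 1 - 1e-15)
  expect_equal(clamp_p(0.5), 0.5)
  expect_equal(clamp_p(c(0, 0.2, 1)), c(1e-15, 0.2, 1 - 1e-15))
  expect_error(clamp_p(-0.1), "\\[0, 1\\]")
  expect_error(clamp_p(1.1), "\\[0, 1\\]")
})

test_that("p_to_signed_z matches the normal quantile and carries the sign", {
  expect_equal(p_to_signed_z(0.5, "up"), 0)
  # high-precision oracle value for the upper 5% normal quantile
  expect_equal(p_to_signed_z(0.05, "up"), 1.64485362695147, tolerance = 1e-12)
  expect_equal(p_to_signed_z(0.05, "down"), -1.64485362695147,
               tolerance = 1e-12)
  expect_equal(p_to_signed_z(c(0.05, 0.05), c("UP", "Down")),
               c(1, -1) * qnorm(0.95))
  expect_error(p_to_signed_z(0, "up"), "strictly inside")
  expect_error(p_to_signed_z(1, "down"), "strictly inside")
  expect_error(p_to_signed_z(0.5, "sideways"), "direction")
})

test_that("p_to_signed_z is monotone in p and antisymmetric in direction", {
  set.seed(42)
  p <- sort(runif(200, 1e-6, 1 - 1e-6))
  z_up <- p_to_signed_z(p, "up")
  expect_true(all(diff(z_up) < 0))        # strictly decreasing
  expect_equal(p_to_signed_z(p, "down"), -z_up)
})

test_that("Stouffer combination reproduces hand-computed values", {
  one <- combine_stouffer(data.frame(gene = "A", z = 1.7))
  expect_equal(one$z, 1.7)
  expect_equal(one$n_studies, 1L)
  two <- combine_stouffer(list(data.frame(gene = "A", z = 1.2),
                               data.frame(gene = "A", z = 2.0)))
  # (1.2 + 2.0)/sqrt(2), frozen from an arbitrary-precision oracle
  expect_equal(two$z, 2.26274169979695, tolerance = 1e-12)
  expect_equal(two$n_studies, 2L)
})

test_that("Stouffer combination obeys the sqrt(N) scaling law", {
  for (N in 1:10) {
    tabs <- replicate(N, data.frame(gene = "A", z = 0.5), simplify = FALSE)
    expect_equal(combine_stouffer(tabs)$z, 0.5 * sqrt(N), tolerance = 1e-12)
  }
})

test_that("Stouffer combination is permutation invariant and handles overlap", {
  set.seed(7)
  tabs <- lapply(1:4, function(i) {
    g <- sample(sprintf("G%02d", 1:15), sample(5:15, 1))
    data.frame(gene = g, z = rnorm(length(g)))
  })
  a <- combine_stouffer(tabs)
  b <- combine_stouffer(rev(tabs))
  expect_equal(a, b)
  # per-gene N equals the number of tables containing the gene
  counts <- table(unlist(lapply(tabs, `[[`, "gene")))
  expect_equal(a$n_studies, as.integer(counts[a$gene]),
               ignore_attr = TRUE)
})

test_that("balance_groups reproduces the two-group worked adjustment", {
  breast <- ztab(c("A", "B"), c(1.0, 2.74), label = "breast")  # mean |Z| 1.87
  lung <- ztab(c("A", "B"), c(-2.0, 3.7), label = "lung")      # mean |Z| 2.85
  bal <- balance_groups(list(breast = breast, lung = lung))
  expect_equal(round(bal$target, 2), 2.36)
  expect_equal(round(unname(bal$factors), 2), c(1.26, 0.83))
  for (t in bal$tables) expect_equal(mean(abs(t$z)), bal$target,
                                     tolerance = 1e-9)
})

test_that("balance_groups fixed points and degenerate groups", {
  a <- ztab(c("A", "B"), c(1, -2), label = "a")
  one <- balance_groups(list(a = a))
  expect_equal(unname(one$factors), 1)
  expect_equal(one$tables$a$z, a$z)
  b <- ztab(c("A", "B"), c(-1.5, 1.5), label = "b")  # same mean |Z| as a
  eq <- balance_groups(list(a = a, b = b))
  expect_equal(unname(eq$factors), c(1, 1))
  zero <- ztab("A", 0)
  expect_error(balance_groups(list(a = a, z = zero)), "degenerate")
})

test_that("balance_groups hits the target and preserves |Z| rank order", {
  set.seed(3)
  groups <- list(g1 = random_ztab(30), g2 = random_ztab(12),
                 g3 = random_ztab(50))
  bal <- balance_groups(groups)
  for (nm in names(groups)) {
    expect_equal(mean(abs(bal$tables[[nm]]$z)), bal$target,
                 tolerance = 1e-9)
    expect_equal(order(abs(bal$tables[[nm]]$z)),
                 order(abs(groups[[nm]]$z)))
  }
  expect_true(all(bal$factors > 0))
})

test_that("contrast_tables subtracts gene-wise and is antisymmetric", {
  a <- ztab(c("A", "B"), c(2.5, 1), c(2L, 3L))
  b <- ztab(c("A", "B"), c(-1.0, 1), c(1L, 1L))
  d <- contrast_tables(a, b)
  expect_equal(d$z[d$gene == "A"], 3.5)
  expect_equal(d$n_studies, c(3L, 4L))
  expect_equal(contrast_tables(a, a)$z, c(0, 0))
  set.seed(9)
  x <- random_ztab(15); y <- random_ztab(15)
  expect_equal(contrast_tables(x, y)$z, -contrast_tables(y, x)$z)
})

test_that("contrast_tables missing-gene policies", {
  a <- ztab(c("A", "B"), c(1, 2))
  b <- ztab(c("B", "C"), c(0.5, 3))
  expect_message(d <- contrast_tables(a, b), "dropped 2")
  expect_equal(d$gene, "B")
  expect_equal(d$z, 1.5)
  zf <- suppressMessages(contrast_tables(a, b, policy = "zero_fill"))
  expect_equal(zf$gene, c("A", "B", "C"))
  expect_equal(zf$z, c(1, 1.5, -3))
})

test_that("average_tables averages shared genes and carries singletons", {
  x <- ztab(c("A", "B"), c(4, 2), c(2L, 2L))
  y <- ztab(c("A", "C"), c(0, 6), c(1L, 1L))
  av <- average_tables(x, y)
  expect_equal(av$gene, c("A", "B", "C"))
  expect_equal(av$z, c(2, 2, 6))          # carry-available on B and C
  expect_equal(av$n_studies, c(3L, 2L, 1L))
  expect_equal(average_tables(x, x)$z, x$z)  # idempotent on equal inputs
  int <- average_tables(x, y, policy = "intersect")
  expect_equal(int$gene, "A")
})

test_that("nested averaging reproduces the 1/4, 1/4, 1/2 weights", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:25)
  a <- random_ztab(25, genes = genes)
  b <- random_ztab(25, genes = genes)
  c_ <- random_ztab(25, genes = genes)
  nested <- average_tables(average_tables(a, b), c_)
  expect_equal(nested$z, a$z / 4 + b$z / 4 + c_$z / 2, tolerance = 1e-12)
})
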