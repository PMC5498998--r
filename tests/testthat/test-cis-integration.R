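make_gct <- function(values, use_cis = TRUE,
                     thresholds = aberration_thresholds()) {
  structure(list(values = values,
                 categories = matrix(call_category(values, thresholds,
                                                   use_cis),
                                     nrow(values), dimnames = dimnames(values)),
                 thresholds = thresholds, use_cis = use_cis),
            class = "gene_copy_table")
}

test_that("expression filters: lower-quartile mean and strict IQR", {
  x <- toy_matrix(rep(1:8, times = 4) + rep(c(-1, -0.5, 0.5, 1), each = 8),
                  n_genes = 8, n_samples = 4)
  ## gene means 1..8: the two lowest fall at/below the 25th percentile
  kept <- filter_expression_for_cis(x, cis_config(iqr_min = 0))
  expect_setequal(kept, rownames(x)[3:8])
  ## IQR exactly at the cutoff is removed (strict >); 0.375 + 0.375 is an
  ## exact binary fraction so the comparison is float-safe
  x2 <- x; x2[3, ] <- 3 + c(-0.375, -0.375, 0.375, 0.375) # IQR 0.75
  kept2 <- filter_expression_for_cis(x2, cis_config(iqr_min = 0.75))
  expect_false("g003" %in% kept2)
  expect_true("g008" %in% kept2)
  ## identical genes: all removed
  x3 <- toy_matrix(rep(5, 8 * 4), n_genes = 8)
  expect_warning(kept3 <- filter_expression_for_cis(x3), "no genes")
  expect_length(kept3, 0)
})

test_that("gene eligibility requires aberration in more than 2 eligible samples", {
  v <- toy_matrix(rep(0, 10 * 18), n_genes = 10, n_samples = 18)
  v[1, 1:3] <- 0.5   # gained in 3 -> eligible
  v[2, 1:2] <- 0.5   # gained in 2 -> not eligible
  v[3, 1:3] <- -0.5  # lost in 3
  v[4, 1:3] <- 0.4; v[4, 4:6] <- -0.6  # both directions
  gct <- make_gct(v)
  expect_setequal(eligible_genes(gct, direction = "gain"), c("g001", "g004"))
  expect_setequal(eligible_genes(gct, direction = "loss"), c("g003", "g004"))
  expect_error(eligible_genes(make_gct(v, use_cis = FALSE)), "use_cis")
  expect_error(
    eligible_genes(gct, cis_config(eligible_samples = "ghost")), "ghost")
})

test_that("Wilcoxon in-cis verdicts: planted dosage, flat nulls, FDR flags", {
  set.seed(20)
  n <- 18
  v <- toy_matrix(rep(0, 40 * n), n_genes = 40, n_samples = n)
  x <- toy_matrix(rnorm(40 * n, 7, 0.3), n_genes = 40, n_samples = n)
  for (g in 1:10) {              # strong planted dosage genes
    carriers <- sample(n, 5)
    v[g, carriers] <- runif(5, 0.5, 0.9)
    x[g, ] <- x[g, ] + v[g, ]
  }
  for (g in 11:30) v[g, sample(n, 4)] <- 0.5   # aberrant but flat expression
  res <- test_cis(x, make_gct(v))
  gain <- res[res$direction == "gain", ]
  expect_setequal(gain$gene, rownames(v)[1:30])
  expect_true(all(gain$wilcoxon_associated[match(rownames(v)[1:10],
                                                 gain$gene)]))
  ## identical expression across samples: p = 1, not associated
  x2 <- x; x2[11, ] <- 5
  res2 <- test_cis(x2, make_gct(v), genes = "g011")
  expect_equal(res2$p, 1)
  expect_false(res2$wilcoxon_associated)
})

test_that("direction symmetry: negating copy number swaps gain and loss results", {
  set.seed(21)
  n <- 12
  v <- toy_matrix(sample(c(0, 0.5, -0.5), 20 * n, replace = TRUE,
                         prob = c(0.6, 0.2, 0.2)), n_genes = 20, n_samples = n)
  x <- toy_matrix(rnorm(20 * n), n_genes = 20, n_samples = n)
  r1 <- test_cis(x, make_gct(v))
  r2 <- test_cis(x, make_gct(-v))
  swap <- c(gain = "loss", loss = "gain")
  for (d in c("gain", "loss")) {
    a <- r1[r1$direction == d, ]
    b <- r2[r2$direction == swap[d], ]
    b <- b[match(a$gene, b$gene), ]
    expect_equal(a$p, b$p)
    expect_equal(a$n_aberrant, b$n_aberrant)
  }
})

test_that("Wilcoxon verdict is invariant under monotone expression transforms", {
  set.seed(22)
  n <- 14
  v <- toy_matrix(rep(0, 5 * n), n_genes = 5, n_samples = n)
  for (g in 1:5) v[g, sample(n, 4)] <- 0.6
  x <- toy_matrix(rnorm(5 * n, 4, 1), n_genes = 5, n_samples = n)
  p1 <- test_cis(x, make_gct(v))$p
  p2 <- test_cis(2^x, make_gct(v))$p
  expect_equal(p1, p2)
})

test_that("Spearman flagging is strict and handles degenerate vectors", {
  n <- 10
  v <- toy_matrix(rep(seq(-0.4, 0.5, 0.1), each = 3), n_genes = 3,
                  n_samples = n)
  x <- 2^v + 5  # monotone in copy number
  rownames(x) <- rownames(v)
  res <- correlate_cis(x, make_gct(v))
  expect_equal(res$rho, rep(1, 3))
  expect_true(all(res$correlation_associated))
  ## monotone transform of both variables leaves rho unchanged
  res2 <- correlate_cis(exp(x), make_gct(sign(v) * sqrt(abs(v))))
  expect_equal(res2$rho, res$rho)
  ## rho exactly at the cutoff is not associated
  cfg <- cis_config(spearman_cut = 1)
  expect_false(any(correlate_cis(x, make_gct(v), cfg)$correlation_associated))
  ## constant copy-number vector: undefined rho, flagged FALSE with message
  vc <- v; vc[1, ] <- 0.2
  expect_message(res3 <- correlate_cis(x, make_gct(vc)), "constant")
  expect_true(is.na(res3$rho[1]))
  expect_false(res3$correlation_associated[1])
})

test_that("null in-cis correlation flags fewer than 5% of independent genes", {
  set.seed(23)
  n <- 18
  v <- toy_matrix(rnorm(1000 * n, 0, 0.3), n_genes = 1000, n_samples = n)
  x <- toy_matrix(rnorm(1000 * n), n_genes = 1000, n_samples = n)
  res <- correlate_cis(x, make_gct(v))
  expect_lt(mean(res$correlation_associated), 0.05)
})

test_that("reporting arithmetic reproduces percentages from counts", {
  expect_equal(percent_of(298, 1148), 26)
  expect_equal(percent_of(229, 1047), 22)
  expect_equal(percent_of(215, 298), 72)
  expect_equal(percent_of(174, 229), 76)
  expect_equal(percent_of(1, 3, digits = 1), 33.3)
  expect_error(percent_of(1, 0), "positive")
})

test_that("cis summary counts eligible, associated and correlated genes", {
  cis <- structure(data.frame(
    gene = c("a", "b", "c", "d"), direction = c("gain", "gain", "gain", "loss"),
    n_aberrant = 3L, p = c(0.001, 0.5, 0.01, 0.9),
    q = c(0.003, 0.5, 0.02, 0.9),
    wilcoxon_associated = c(TRUE, FALSE, TRUE, FALSE)),
    class = c("cis_result", "data.frame"))
  corr <- data.frame(gene = c("a", "b", "c", "d"), rho = c(0.9, 0.1, 0.5, 0),
                     n = 10L, correlation_associated = c(TRUE, FALSE, FALSE,
                                                         FALSE))
  s <- cis_association_summary(cis, corr)
  g <- s[s$direction == "gain", ]
  expect_equal(g$n_eligible, 3L)
  expect_equal(g$n_associated, 2L)
  expect_equal(g$pct_associated, 67)
  expect_equal(g$n_correlated, 1L)
  expect_equal(g$pct_correlated, 50)
})
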