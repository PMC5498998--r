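test_that("variable-gene selection ranks by variance with stable ties", {
  set.seed(1)
  x <- toy_matrix(rnorm(100 * 6), n_samples = 6)
  x[1:10, ] <- 0  # zero variance
  sel <- select_variable_genes(x, 90)
  expect_false(any(rownames(x)[1:10] %in% rownames(sel)))
  expect_identical(select_variable_genes(x, nrow(x)), x)
  expect_error(select_variable_genes(x, 0), "positive")
  expect_error(select_variable_genes(x, 1000), "exceeds")
  ## planted high-variance markers are all selected
  x[11:20, 1:3] <- x[11:20, 1:3] + 50
  sel <- select_variable_genes(x, 10)
  expect_setequal(rownames(sel), rownames(x)[11:20])
})

test_that("PCA scores: centering, rank-1 variance, marker orientation", {
  set.seed(2)
  x <- toy_matrix(rnorm(20 * 2), n_samples = 2)
  sc <- pca_scores(x)$scores
  expect_equal(sc[1, 1], -sc[2, 1])
  ## rank-1 matrix: PC1 explains all variance
  x1 <- outer(rnorm(30), rnorm(8)) + 5
  rownames(x1) <- sprintf("g%02d", 1:30); colnames(x1) <- sprintf("s%d", 1:8)
  expect_equal(pca_scores(x1)$var_explained[1], 1)
  expect_error(pca_scores(toy_matrix(rep(1, 40), n_samples = 4)), "constant")
  ## marker orientation: high-marker samples get low PC1
  x2 <- toy_matrix(rnorm(200 * 10, 5, 0.2), n_samples = 10)
  markers <- rownames(x2)[1:40]
  x2[markers, 1:5] <- x2[markers, 1:5] + 3
  pc <- pca_scores(x2, marker_set = markers)$scores[, 1]
  expect_true(max(pc[1:5]) < min(pc[6:10]))
})

test_that("bimodal split finds the between-peaks minimum and flags unimodality", {
  set.seed(3)
  ok <- 0; exact <- 0
  for (i in 1:30) {
    sc <- setNames(c(rnorm(15, -3), rnorm(15, 3)), sprintf("s%02d", 1:30))
    sp <- bimodal_split(sc)
    if (isTRUE(attr(sp, "bimodality_ok")) &&
        attr(sp, "threshold") > -1.5 && attr(sp, "threshold") < 1.5) {
      ok <- ok + 1
      if (all(sp$label == rep(c("colon_like", "undifferentiated"), each = 15)))
        exact <- exact + 1
    }
  }
  expect_gte(ok, 27)
  ## occasional samples falling between well-separated modes may land on the
  ## wrong side of the estimated minimum; the vast majority must not
  expect_gte(exact, round(0.85 * ok))
  ## degenerate and unimodal inputs
  sp <- bimodal_split(setNames(rep(1, 8), letters[1:8]))
  expect_false(attr(sp, "bimodality_ok"))
  expect_true(all(is.na(sp$label)))
  expect_error(bimodal_split(rnorm(5)), "6 samples")
})

test_that("trimodal input splits between the two highest peaks", {
  ## outer modes are the two highest; threshold must fall between them,
  ## at the lowest of the minima flanking the small middle mode
  set.seed(4)
  sc <- setNames(c(rnorm(20, -6, 0.5), rnorm(5, 0, 0.3), rnorm(20, 6, 0.5)),
                 sprintf("s%02d", 1:45))
  sp <- bimodal_split(sc)
  expect_true(attr(sp, "bimodality_ok"))
  expect_gt(attr(sp, "threshold"), -6)
  expect_lt(attr(sp, "threshold"), 6)
  ## all left-mode samples on one side, right-mode on the other
  expect_true(all(sp$label[1:20] == "colon_like"))
  expect_true(all(sp$label[26:45] == "undifferentiated"))
})

test_that("adding a far one-sided sample does not relabel the others", {
  set.seed(5)
  sc <- setNames(c(rnorm(10, -4), rnorm(10, 4)), sprintf("s%02d", 1:20))
  base <- bimodal_split(sc)
  ext <- bimodal_split(c(sc, far = 12))
  expect_equal(ext$label[match(names(sc), ext$sample_id)], base$label)
})

test_that("ssGSEA running sum: sign, hand-computed value, rank invariance", {
  x <- toy_matrix(c(5, 4, 3, 2, 1), n_samples = 1)
  ## top-2 set positive, bottom-2 set negative
  expect_gt(ssgsea_score(x, c("g001", "g002"), alpha = 0), 0)
  expect_lt(ssgsea_score(x, c("g004", "g005"), alpha = 0), 0)
  ## hand enumeration, alpha = 0, set {g001, g004}:
  ## P_in = 1/2,1/2,1/2,1,1; P_out = 0,1/3,2/3,2/3,1; ES = 5/6
  expect_equal(unname(ssgsea_score(x, c("g001", "g004"), alpha = 0)), 5 / 6)
  ## alpha = 0 scores depend only on ranks
  set.seed(6)
  m <- toy_matrix(rnorm(50 * 4), n_samples = 4)
  s1 <- ssgsea_score(m, rownames(m)[1:10], alpha = 0)
  s2 <- ssgsea_score(2^m + 7, rownames(m)[1:10], alpha = 0)
  expect_equal(s1, s2)
  expect_error(ssgsea_score(m, "absent"), "no overlap")
  expect_error(ssgsea_score(m, rownames(m)), "proper subset")
  expect_error(ssgsea_score(m, rownames(m)[1:2], alpha = -1), "alpha")
})

test_that("moderated t shrinks variances and matches limma", {
  set.seed(7)
  x <- toy_matrix(rnorm(200 * 12), n_samples = 12)
  labels <- rep(c("A", "B"), each = 6)
  x[1:20, labels == "B"] <- x[1:20, labels == "B"] + 2
  de <- differential_expression(x, labels)
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, labels == "B")))
  expect_gt(cor(de$t, fit$t[, 2]), 0.9999)
  expect_equal(attr(de, "df_prior"), fit$df.prior, tolerance = 0.05)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-4)
  ## welch cross-check agrees in direction and roughly in magnitude
  dew <- differential_expression(x, labels, method = "welch")
  expect_gt(cor(de$t, dew$t), 0.95)
})

test_that("degenerate features and the infinite-prior limit", {
  set.seed(8)
  x <- toy_matrix(rnorm(50 * 8), n_samples = 8)
  x[1, ] <- 3  # constant feature
  labels <- rep(c("A", "B"), each = 4)
  de <- differential_expression(x, labels)
  expect_equal(de$log2FC[1], 0)
  expect_equal(de$p[1], 1)
  ## prior weight -> infinity: every moderated variance equals the prior
  de2 <- differential_expression(x, labels, prior_df = Inf, prior_var = 0.5)
  se <- de2$log2FC / de2$t
  expect_equal(unname(se[is.finite(se)]),
               rep(sqrt(0.5 * (1 / 4 + 1 / 4)), sum(is.finite(se))),
               tolerance = 1e-10)
  expect_error(differential_expression(x, rep("A", 8)), "two levels")
  expect_error(differential_expression(x[, 1:3], c("A", "A", "B")), "at least 2")
})

test_that("BH q-values are monotone in p-rank and bounded by 1", {
  set.seed(9)
  x <- toy_matrix(rnorm(300 * 10), n_samples = 10)
  de <- differential_expression(x, rep(c("A", "B"), each = 5))
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-12))
  expect_lte(max(de$q), 1)
  expect_gte(de$q[o][1], de$p[o][1])
})

test_that("moderated-t pipeline recovers planted shifts with controlled FDR", {
  set.seed(10)
  sens <- fdr <- numeric(10)
  for (i in 1:10) {
    x <- toy_matrix(rnorm(550 * 30), n_samples = 30)
    labels <- rep(c("A", "B"), each = 15)
    x[1:50, labels == "B"] <- x[1:50, labels == "B"] + 2
    de <- differential_expression(x, labels)
    disc <- de$feature[de$q < 0.05]
    sens[i] <- mean(rownames(x)[1:50] %in% disc)
    fdr[i] <- if (length(disc)) mean(!disc %in% rownames(x)[1:50]) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})

test_that("competitive gene set test: extreme sets, null uniformity, symmetry", {
  set.seed(11)
  x <- toy_matrix(rnorm(1000 * 16), n_samples = 16)
  de <- differential_expression(x, rep(c("A", "B"), each = 8))
  top <- de$feature[order(-de$t)][1:50]
  res <- competitive_gene_set_test(de, list(top = top))
  expect_lt(res$p, 1e-6)
  ## null sets give approximately uniform p-values
  sets <- setNames(lapply(1:200, function(i) sample(de$feature, 20)),
                   paste0("set", 1:200))
  resn <- competitive_gene_set_test(de, sets)
  expect_gt(suppressWarnings(ks.test(resn$p, "punif"))$p.value, 0.01)
  ## a set and its complement give the same p-value (role symmetry)
  half <- de$feature[1:500]
  r2 <- competitive_gene_set_test(de, list(a = half,
                                           b = setdiff(de$feature, half)))
  expect_equal(r2$p[1], r2$p[2])
  expect_message(competitive_gene_set_test(de, list(x = "nope", top = top)),
                 "no overlap")
})

test_that("miRNA log-CPM normalization and planted fold-change recovery", {
  counts <- toy_matrix(c(0, 10, 0, 20, 0, 30, 0, 40), n_genes = 2)
  expect_error(normalize_mirna(counts - 1), "negative")
  lc <- normalize_mirna(counts)
  ## all-zero feature tracks the per-sample floor
  expect_equal(lc[1, ], log2(0.5 / (colSums(counts) + 1) * 1e6),
               ignore_attr = TRUE)
  ## doubling all counts (library size) leaves log-CPM nearly unchanged
  lc2 <- normalize_mirna(counts * 2)
  expect_equal(lc[2, ], lc2[2, ], tolerance = 0.01)
  ## planted 4-fold differences (balanced up/down) recovered within +-0.3
  set.seed(12)
  err <- replicate(3, {
    mu <- exp(rnorm(400, log(500), 0.5))
    g <- rep(c(0, 1), each = 10)
    fold <- rep(1, 400); fold[1:10] <- 4; fold[11:20] <- 0.25
    m <- sapply(g, function(gi)
      rnbinom(400, mu = if (gi == 1) mu * fold else mu, size = 10))
    rownames(m) <- sprintf("m%03d", 1:400); colnames(m) <- sprintf("s%02d", 1:20)
    lcp <- normalize_mirna(m, cyclic_loess = TRUE)
    fc <- rowMeans(lcp[, g == 1]) - rowMeans(lcp[, g == 0])
    c(median(fc[1:10]) - 2, median(fc[11:20]) + 2)
  })
  expect_lt(max(abs(err)), 0.3)
})
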