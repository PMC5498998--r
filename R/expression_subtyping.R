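#' Select the most variable features
#'
#' Keeps the `n` features with the largest cross-sample variation. Ties are
#' broken by row order of the input matrix.
#'
#' @param x Numeric matrix, features x samples.
#' @param n Number of features to keep.
#' @param measure Variation measure: variance (default), standard deviation
#'   or median absolute deviation. Variance and SD induce the same ranking;
#'   both are offered for explicitness.
#' @return The row-subset matrix (original row order preserved).
#' @export
select_variable_genes <- function(x, n = 1000,
                                  measure = c("variance", "sd", "mad")) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(x))
  if (n <= 0) stop("select_variable_genes: n must be positive")
  if (n > nrow(x)) stop("select_variable_genes: n exceeds feature count")
  v <- switch(measure,
              variance = apply(x, 1, stats::var),
              sd = apply(x, 1, stats::sd),
              mad = apply(x, 1, stats::mad))
  keep <- sort(order(-v, seq_len(nrow(x)))[seq_len(n)])
  x[keep, , drop = FALSE]
}

#' Principal component scores of an expression matrix
#'
#' Singular value decomposition of the gene-centered (optionally scaled)
#' matrix. The PC1 orientation is fixed: if a marker gene set is supplied,
#' the sign is chosen so that samples with higher mean marker expression get
#' *lower* PC1 scores (the "colon-like = low PC1" convention); otherwise the
#' loading with the largest magnitude is made positive. Other components use
#' the loading rule.
#'
#' @param x Numeric matrix, features x samples (log2 scale).
#' @param marker_set Optional character vector of marker feature ids.
#' @param scale. Scale features to unit variance before the SVD.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `sdev` and `var_explained`.
#' @export
pca_scores <- function(x, marker_set = NULL, scale. = FALSE) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2 || nrow(x) < 2)
    stop("pca_scores: need at least 2 features and 2 samples")
  v <- apply(x, 1, stats::var)
  if (all(v == 0)) stop("pca_scores: constant matrix")
  if (scale.) {
    keep <- v > 0
    x <- x[keep, , drop = FALSE]
    v <- v[keep]
  }
  xc <- x - rowMeans(x)
  if (scale.) xc <- xc / sqrt(v)
  sv <- svd(t(xc))
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  rownames(scores) <- colnames(x)
  rownames(loadings) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
  for (k in seq_len(ncol(scores))) {
    flip <- FALSE
    if (k == 1L && !is.null(marker_set)) {
      ms <- intersect(marker_set, rownames(x))
      if (!length(ms)) stop("pca_scores: marker_set has no overlap with features")
      marker_mean <- colMeans(x[ms, , drop = FALSE])
      flip <- stats::cor(scores[, 1L], marker_mean) > 0
    } else {
      flip <- loadings[which.max(abs(loadings[, k])), k] < 0
    }
    if (isTRUE(flip)) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  sdev <- sv$d / sqrt(max(1, ncol(x) - 1))
  list(scores = scores, loadings = loadings, sdev = sdev,
       var_explained = sv$d^2 / sum(sv$d^2))
}

#' Split samples at the between-peaks minimum of the PC1 density
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth by
#' default) to the PC1 scores. If the density has at least two local maxima,
#' the threshold is the score of the lowest local minimum between the two
#' highest maxima; samples at or below the threshold are labelled
#' `colon_like` (low PC1) and the rest `undifferentiated`. The distribution
#' is accepted as bimodal only when that between-peaks minimum is genuinely
#' depressed - below `dip_ratio` times the smaller of the two peak heights -
#' which suppresses the spurious density wiggles finite samples produce.
#' Otherwise no labels are assigned and `bimodality_ok` is `FALSE`. Ties
#' among equally high peaks are broken towards the leftmost peaks.
#'
#' @param pc1_scores Named numeric vector of PC1 scores (>= 6 samples).
#' @param bw Kernel bandwidth passed to `stats::density`.
#' @param dip_ratio Maximum ratio of the between-peaks minimum to the smaller
#'   peak height for the split to be accepted.
#' @return Object of class `subtype_call`: data frame with `sample_id`,
#'   `pc1_score`, `label`; attributes `threshold` and `bimodality_ok`.
#' @export
bimodal_split <- function(pc1_scores, bw = "nrd0", dip_ratio = 0.75) {
  if (length(pc1_scores) < 6) stop("bimodal_split: need at least 6 samples")
  ids <- names(pc1_scores)
  if (is.null(ids)) ids <- paste0("S", seq_along(pc1_scores))
  threshold <- NA_real_
  ok <- FALSE
  if (stats::sd(pc1_scores) > 0) {
    d <- stats::density(pc1_scores, bw = bw)
    y <- d$y
    i <- 2:(length(y) - 1L)
    maxima <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
    if (length(maxima) >= 2L) {
      top2 <- sort(maxima[order(-y[maxima], maxima)][1:2])
      between <- (top2[1L] + 1L):(top2[2L] - 1L)
      minima <- between[y[between] <= y[between - 1L] & y[between] < y[between + 1L]]
      if (!length(minima)) minima <- between[which.min(y[between])]
      if (min(y[minima]) < dip_ratio * min(y[top2])) {
        threshold <- d$x[minima[which.min(y[minima])]]
        ok <- TRUE
      }
    }
  }
  label <- if (ok) {
    ifelse(pc1_scores <= threshold, "colon_like", "undifferentiated")
  } else rep(NA_character_, length(pc1_scores))
  out <- data.frame(sample_id = ids, pc1_score = unname(pc1_scores),
                    label = label, stringsAsFactors = FALSE)
  structure(out, threshold = threshold, bimodality_ok = ok,
            class = c("subtype_call", class(out)))
}

ssgsea_one <- function(v, in_set, alpha) {
  n <- length(v)
  ord <- order(v, decreasing = TRUE)
  inq <- in_set[ord]
  rk <- n - rank(v, ties.method = "first") + 1  # 1 = highest expression
  w <- (n - rk + 1)^alpha                       # rank-normalized weight
  w <- w[ord]
  w[!inq] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inq) / sum(!inq)
  sum(p_in - p_out)
}

#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For each sample, features are ranked by expression (descending) and the
#' score is the sum over the ranked list of the difference between the
#' weighted in-set cumulative fraction and the uniform out-set cumulative
#' fraction. In-set weights are the rank-normalized values raised to `alpha`
#' (with `alpha = 0` the running sum is unweighted and the score depends only
#' on ranks). Optionally, scores are normalized by their range across
#' samples.
#'
#' @param x Numeric matrix, features x samples.
#' @param gene_set Character vector of feature ids; must overlap the features
#'   and be a proper subset of them.
#' @param alpha Weighting exponent (>= 0); default 0.25.
#' @param normalize Divide scores by `max - min` across samples.
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(x, gene_set, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(x))
  if (alpha < 0) stop("ssgsea_score: alpha must be >= 0")
  in_set <- rownames(x) %in% gene_set
  if (!any(in_set)) stop("ssgsea_score: gene set has no overlap with features")
  if (all(in_set)) stop("ssgsea_score: gene set must be a proper subset of features")
  scores <- apply(x, 2, ssgsea_one, in_set = in_set, alpha = alpha)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

## method-of-moments fit of a scaled inverse-chi-square prior to gene-wise
## variances on the log scale; returns df.prior and var.prior
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  ok <- is.finite(z)
  if (sum(ok) < 2) return(list(df = Inf, var = mean(s2[ok], na.rm = TRUE)))
  e <- z[ok] - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df = d0, var = s02)
}

#' Two-group differential expression with a moderated t-statistic
#'
#' For each feature the log2 fold-change is the difference of group means
#' (second factor level minus first). Gene-wise pooled variances are shrunk
#' towards a common prior fitted by the standard empirical-Bayes
#' method-of-moments on log variances; the moderated t uses the augmented
#' degrees of freedom. A plain Welch t-test is available for cross-checking.
#'
#' @param x Numeric matrix, features x samples (log2 scale).
#' @param labels Factor (or coercible) of length `ncol(x)` with two levels,
#'   each with at least 2 samples.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param prior_df,prior_var Optional overrides of the fitted prior; with
#'   `prior_df = Inf` every moderated variance equals `prior_var`.
#' @return Object of class `de_result`: data frame with `feature`, `log2FC`,
#'   `t`, `p`, `q` (Benjamini-Hochberg); attributes `df_prior`, `var_prior`.
#' @export
differential_expression <- function(x, labels,
                                    method = c("moderated", "welch"),
                                    prior_df = NULL, prior_var = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(x))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("differential_expression: labels must have exactly two levels")
  if (any(table(labels) < 2))
    stop("differential_expression: each group needs at least 2 samples")
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  fc <- m2 - m1
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, g2, drop = FALSE], 1, stats::var)
  if (method == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- fc / se
    df_w <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df_w)
    p[!is.finite(tt)] <- 1
    tt[!is.finite(tt)] <- 0
    res <- data.frame(feature = rownames(x), log2FC = fc, t = tt, p = p,
                      q = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    return(structure(res, df_prior = NA_real_, var_prior = NA_real_,
                     class = c("de_result", class(res))))
  }
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  prior <- fit_variance_prior(s2[s2 > 0], df)
  if (!is.null(prior_df)) prior$df <- prior_df
  if (!is.null(prior_var)) prior$var <- prior_var
  s2_post <- if (is.infinite(prior$df)) rep(prior$var, length(s2)) else
    (prior$df * prior$var + df * s2) / (prior$df + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, fc / se, 0)
  df_total <- df + prior$df
  p <- 2 * stats::pt(-abs(tt), df_total)
  res <- data.frame(feature = rownames(x), log2FC = fc, t = tt, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, df_prior = prior$df, var_prior = prior$var,
            class = c("de_result", class(res)))
}

#' Competitive gene set test on moderated t-statistics
#'
#' For each gene set, a two-sided Wilcoxon rank-sum test compares the
#' moderated t-statistics of in-set features against all other features,
#' followed by Benjamini-Hochberg adjustment across sets. This is a
#' rank-based competitive test; it does not apply an inter-gene-correlation
#' variance-inflation adjustment and is anti-conservative when in-set genes
#' are strongly correlated.
#'
#' @param de A `de_result` from [differential_expression()].
#' @param gene_sets Named list of feature-id vectors.
#' @param min_size Minimum number of set members present among the features.
#' @return Data frame with `set`, `n_genes`, `direction` (sign of the median
#'   in-set minus out-set t difference), `p`, `q`. Sets with no overlap are
#'   skipped with a message.
#' @export
competitive_gene_set_test <- function(de, gene_sets, min_size = 5) {
  stopifnot(inherits(de, "de_result"), is.list(gene_sets))
  rows <- list()
  for (nm in names(gene_sets)) {
    members <- intersect(gene_sets[[nm]], de$feature)
    if (!length(members)) {
      message("competitive_gene_set_test: set '", nm, "' has no overlap; skipped")
      next
    }
    if (length(members) < min_size) {
      message("competitive_gene_set_test: set '", nm, "' below min_size; skipped")
      next
    }
    inq <- de$feature %in% members
    wt <- suppressWarnings(stats::wilcox.test(de$t[inq], de$t[!inq],
                                              exact = FALSE, correct = TRUE))
    rows[[nm]] <- data.frame(
      set = nm, n_genes = length(members),
      direction = sign(stats::median(de$t[inq]) - stats::median(de$t[!inq])),
      p = wt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("competitive_gene_set_test: no testable sets")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Normalize a miRNA count matrix to log2 counts-per-million
#'
#' log2-CPM with a 0.5 pseudocount on counts and +1 on library sizes, with an
#' optional cyclic-loess pairwise normalization pass.
#'
#' @param counts Non-negative count matrix, miRNAs x samples.
#' @param cyclic_loess Apply `limma::normalizeCyclicLoess` to the log-CPM.
#' @return Numeric matrix on the log2 scale.
#' @export
normalize_mirna <- function(counts, cyclic_loess = FALSE) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("normalize_mirna: negative counts")
  lib <- colSums(counts)
  logcpm <- log2(t((t(counts) + 0.5) / (lib + 1) * 1e6))
  if (cyclic_loess) logcpm <- limma::normalizeCyclicLoess(logcpm)
  logcpm
}
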