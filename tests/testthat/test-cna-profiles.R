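test_that("PCF segmentation solves forced and degenerate cases exactly", {
  ## constant signal: one segment regardless of gamma
  tr <- data.frame(chrom = "chr1", pos = 0:19 * 100, value = rep(0.42, 20))
  seg <- pcf_segment(tr, gamma = 100)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$pcf_value, 0.42)
  expect_equal(seg$n_probes, 20L)
  expect_equal(c(seg$start, seg$end), c(0L, 1901L))

  ## clean step: penalty 1 is far below the SSE reduction of 25
  tr <- data.frame(chrom = "chr1", pos = 0:99,
                   value = rep(c(0, 1), each = 50))
  seg <- pcf_segment(tr, gamma = 1)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$pcf_value, c(0, 1))
  expect_equal(seg$n_probes, c(50L, 50L))
  expect_equal(seg$end[1L], 50L)  # boundary between probes 49 and 50

  ## very large gamma: single segment at the global mean
  set.seed(11)
  y <- rnorm(60)
  tr <- data.frame(chrom = "chr1", pos = seq_along(y), value = y)
  seg <- pcf_segment(tr, gamma = 1e6, standardize = FALSE)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$pcf_value, mean(y))
})

test_that("PCF dynamic program matches the exhaustive-search optimum", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    y <- rnorm(n) + rep(c(0, sample(c(-2, 0, 2), 1)), length.out = n)
    gamma <- runif(1, 0.1, 5)
    seg <- pcf_segment(data.frame(chrom = "c", pos = seq_len(n), value = y),
                       gamma = gamma, standardize = FALSE)
    starts <- cumsum(c(1L, seg$n_probes))[seq_len(nrow(seg))]
    dp_cost <- sum(vapply(seq_len(nrow(seg)), function(k) {
      idx <- starts[k]:(starts[k] + seg$n_probes[k] - 1L)
      sum((y[idx] - mean(y[idx]))^2)
    }, numeric(1))) + gamma * (nrow(seg) - 1L)
    expect_equal(dp_cost, brute_force_pcf_cost(y, gamma), tolerance = 1e-10)
  }
})

test_that("PCF rejects unordered probes and drops non-finite values", {
  tr <- data.frame(chrom = "chr1", pos = c(2, 1, 3), value = c(1, 2, 3))
  expect_error(pcf_segment(tr), "ordered")
  tr <- data.frame(chrom = "chr1", pos = 1:10,
                   value = c(rep(1, 5), NaN, rep(1, 4)))
  expect_message(seg <- pcf_segment(tr), "non-finite")
  expect_equal(sum(seg$n_probes), 9L)
})

test_that("gain/loss calling uses inclusive thresholds, cis when requested", {
  th <- aberration_thresholds()
  expect_equal(call_category(0.15, th), "gain")
  expect_equal(call_category(-0.15, th), "loss")
  expect_equal(call_category(0.149, th), "neutral")
  expect_equal(call_category(0.29, th, use_cis = TRUE), "neutral")
  expect_equal(call_category(0.3, th, use_cis = TRUE), "gain")
  expect_equal(call_category(c(-0.3, NA), th, use_cis = TRUE),
               c("loss", "missing"))
  expect_error(aberration_thresholds(gain = -0.1), "loss < 0 < gain")
  expect_error(aberration_thresholds(cis_gain = 0.1), "extreme")
})

test_that("genome fraction aberrant excludes uncovered bases", {
  seg <- make_segments("s1", "chr1", c(0, 40), c(40, 100), c(0.5, 0))
  expect_equal(unname(genome_fraction_aberrant(seg)), 40)
  seg <- make_segments("s1", "chr1", c(0, 50), c(50, 100), c(0.1, -0.1))
  expect_equal(unname(genome_fraction_aberrant(seg)), 0)
  ## uncovered [60, 100) excluded from the denominator
  seg <- make_segments("s1", "chr1", c(0, 100), c(60, 140), c(-0.4, 0))
  expect_equal(unname(genome_fraction_aberrant(seg)), 60)
  ## bounds: all aberrant = 100
  seg <- make_segments("s1", "chr1", 0, 10, 2)
  expect_equal(unname(genome_fraction_aberrant(seg)), 100)
  expect_error(genome_fraction_aberrant(make_segments("s1", "chr1", 5, 5, 1)),
               "degenerate")
})

test_that("SRO construction inherits parent values and matches a per-base oracle", {
  ## one sample: SROs identical to its segments
  seg <- make_segments("s1", "chr1", c(0, 100), c(100, 250), c(0.3, -0.2))
  sro <- compute_sro(seg)
  expect_equal(sro$regions$start, c(0, 100))
  expect_equal(sro$regions$end, c(100, 250))
  expect_equal(unname(sro$values[, "s1"]), c(0.3, -0.2))

  ## two samples with different breakpoints over [0, 200)
  seg <- rbind(make_segments("A", "chr1", c(0, 100), c(100, 200), c(1, 2)),
               make_segments("B", "chr1", c(0, 150), c(150, 200), c(5, 6)))
  sro <- compute_sro(seg)
  expect_equal(sro$regions$start, c(0, 100, 150))
  expect_equal(unname(sro$values[, "A"]), c(1, 2, 2))
  expect_equal(unname(sro$values[, "B"]), c(5, 5, 6))

  ## random instances: per-base equality with the lookup oracle
  set.seed(7)
  for (rep in 1:15) {
    segs <- do.call(rbind, lapply(c("sA", "sB", "sC"), function(s) {
      cuts <- sort(sample(1:99, sample(1:4, 1)))
      bounds <- c(0, cuts, 100)
      keep <- runif(length(bounds) - 1) < 0.9  # allow uncovered gaps
      make_segments(s, "chr1", bounds[-length(bounds)][keep],
                    bounds[-1][keep], round(rnorm(sum(keep)), 2))
    }))
    sro <- compute_sro(segs)
    for (q in sample(0:99, 20)) {
      row <- which(sro$regions$start <= q & sro$regions$end > q)
      for (s in c("sA", "sB", "sC")) {
        want <- sro_base_oracle(segs, "chr1", q, s)
        got <- if (length(row)) unname(sro$values[row, s]) else NA_real_
        expect_identical(is.na(got), is.na(want))
        if (!is.na(want)) expect_equal(got, want)
      }
    }
  }
})

test_that("merging equal-valued adjacent SROs recovers the segmentation", {
  set.seed(8)
  segs <- do.call(rbind, lapply(c("x", "y"), function(s) {
    cuts <- sort(sample(1:199, 5))
    bounds <- c(0, cuts, 200)
    make_segments(s, "chr1", bounds[-length(bounds)], bounds[-1],
                  rnorm(length(bounds) - 1))
  }))
  sro <- compute_sro(segs)
  for (s in c("x", "y")) {
    v <- sro$values[, s]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts_i <- c(1, ends[-length(ends)] + 1)
    rec <- data.frame(start = sro$regions$start[starts_i],
                      end = sro$regions$end[ends], value = r$values)
    orig <- segs[segs$sample_id == s, ]
    expect_equal(rec$start, orig$start)
    expect_equal(rec$end, orig$end)
    expect_equal(rec$value, orig$pcf_value)
  }
})

test_that("gene mapping applies the single/consistent/mixed segment rules", {
  genes <- data.frame(gene = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(10, 90, 240), end = c(40, 250, 300))
  seg <- make_segments("s1", "chr1", c(0, 80, 150, 220), c(80, 150, 220, 320),
                       c(0.5, -0.4, 0.1, 0.5))
  th <- aberration_thresholds()
  ## g1 inside one gained segment (cis thresholds)
  gct <- map_genes(seg, genes, th, use_cis = TRUE)
  expect_equal(gct$values["g1", "s1"], 0.5)
  expect_equal(gct$categories["g1", "s1"], "gain")
  ## g2 spans loss/neutral/gain -> median 0.1 -> neutral
  expect_equal(gct$values["g2", "s1"], 0.1)
  expect_equal(gct$categories["g2", "s1"], "neutral")
  ## consistent category, median value
  seg2 <- make_segments("s1", "chr1", c(0, 50), c(50, 120), c(0.35, 0.6))
  genes2 <- data.frame(gene = "g", chrom = "chr1", start = 20, end = 100)
  gct2 <- map_genes(seg2, genes2, th, use_cis = TRUE)
  expect_equal(gct2$values["g", "s1"], 0.475)
  expect_equal(gct2$categories["g", "s1"], "gain")
  ## coverage-weighted alternative: 30 bases at 0.35, 50 at 0.6
  gct3 <- map_genes(seg2, genes2, th, use_cis = TRUE,
                    value_method = "weighted_mean")
  expect_equal(gct3$values["g", "s1"], (30 * 0.35 + 50 * 0.6) / 80)
  ## no overlap -> missing; unknown requested gene -> error listing it
  gct4 <- map_genes(seg2, genes, th)
  expect_equal(gct4$categories["g3", "s1"], "missing")
  expect_true(is.na(gct4$values["g3", "s1"]))
  expect_error(map_genes(seg2, genes2, th, genes = c("g", "nope")), "nope")
})

test_that("all-samples filter and group aberration frequencies", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      start = c(0, 150), end = c(50, 200))
  seg <- rbind(make_segments("s1", "chr1", 0, 100, 0.5),
               make_segments("s2", "chr1", 0, 200, 0.5),
               make_segments("s3", "chr1", 0, 200, -0.5))
  gct <- map_genes(seg, genes)
  expect_equal(sort(rownames(filter_genes_all_samples(gct)$values)), "g1")

  freq <- aberration_frequency(gct, list(a = c("s1", "s2"), b = "s3"))
  expect_equal(freq$gain_a[freq$region == "g1"], 1)
  expect_equal(freq$loss_b[freq$region == "g1"], 1)
  expect_equal(freq$gain_diff[freq$region == "g1"], 1)
  ## identical groups: difference 0 everywhere
  freq2 <- aberration_frequency(gct, list(a = c("s1", "s3"), b = c("s1", "s3")))
  expect_true(all(freq2$gain_diff == 0) && all(freq2$loss_diff == 0))
  expect_error(aberration_frequency(gct, list(a = character(0))), "empty")
})
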