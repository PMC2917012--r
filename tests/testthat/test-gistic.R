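test_that("G scores follow the capped threshold-excess sum", {
  pr <- tiny_probes(10)
  thr <- data.frame(sample = c("A", "B"), gain_thr = c(0.2, 0.1),
                    loss_thr = c(-0.2, -0.1))
  # null cohort: G identically zero
  X0 <- matrix(0, 10, 2, dimnames = list(pr$probe, c("A", "B")))
  expect_true(all(gscores(X0, thr, "gain")$G == 0))
  # one sample with one segment at +1.0 over threshold 0.2
  X1 <- X0
  X1[3:6, "A"] <- 1.0
  g <- gscores(X1, thr, "gain")$G
  expect_equal(unname(g[3:6]), rep(0.8, 4))
  expect_equal(unname(g[-(3:6)]), rep(0, 6))
  # amplitude cap applies; loss direction is symmetric
  X2 <- X0
  X2[1, "A"] <- 5
  expect_equal(unname(gscores(X2, thr, "gain", cap = 2)$G[1]), 1.8)
  X3 <- X0
  X3[2, "B"] <- -3
  expect_equal(unname(gscores(X3, thr, "loss", cap = 2)$G[2]), 1.9)
  # random cohorts match the brute-force oracle; sample order irrelevant
  set.seed(13)
  X <- matrix(rnorm(20, 0, 0.6), 10, 2, dimnames = dimnames(X0))
  X[sample(20, 3)] <- NA
  for (dir in c("gain", "loss")) {
    expect_equal(unname(gscores(X, thr, dir)$G),
                 oracle_gscores(X, thr, dir))
  }
  perm <- c(2, 1)
  gp <- gscores(X[, perm], thr[perm, ], "gain")$G
  expect_equal(gp, gscores(X, thr, "gain")$G)
})

test_that("q-values are BH-monotone in G and null cohorts stay empty", {
  pr <- tiny_probes(200)
  set.seed(31)
  X <- matrix(rnorm(200 * 10, 0, 0.05), 200, 10,
              dimnames = list(pr$probe, sprintf("S%02d", 1:10)))
  X[40:60, 1:6] <- X[40:60, 1:6] + 1.2
  thr <- data.frame(sample = colnames(X), gain_thr = 0.2, loss_thr = -0.2)
  sc <- gscores(X, thr, "gain")
  nq <- marker_null_and_q(sc, gistic_config(n_permutations = 200))
  ord <- order(sc$G, decreasing = TRUE)
  expect_true(all(diff(nq$q[ord]) >= -1e-12))
  expect_true(all(nq$q[40:60] < 0.25))
  # all-zero G short-circuits to p = q = 1
  sc0 <- gscores(matrix(0, 200, 10, dimnames = dimnames(X)), thr, "gain")
  nq0 <- marker_null_and_q(sc0, gistic_config(n_permutations = 200))
  expect_true(all(nq0$q == 1))
})

test_that("uniform shared aberrations delineate the exact wide region", {
  # every sample carries the same aberration at zero noise: the wide
  # region equals the aberrant probe span exactly
  pr <- tiny_probes(100)
  X <- matrix(0, 100, 8, dimnames = list(pr$probe, sprintf("S%d", 1:8)))
  X[30:45, ] <- 1.5
  thr <- data.frame(sample = colnames(X), gain_thr = 0.2, loss_thr = -0.2)
  set.seed(9)
  sc <- gscores(X, thr, "gain")
  nq <- marker_null_and_q(sc, gistic_config(n_permutations = 300))
  reg <- significant_regions(sc, nq, pr, gistic_config(n_permutations = 300))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$wide_start, pr$start[30])
  expect_equal(reg$wide_end, pr$end[45])
  expect_gte(reg$peak_start, pr$start[30])
  expect_lte(reg$peak_end, pr$end[45])
})

test_that("peel-off separates two amplicons on one chromosome", {
  pr <- tiny_probes(200)
  set.seed(17)
  X <- matrix(rnorm(200 * 40, 0, 0.03), 200, 40,
              dimnames = list(pr$probe, sprintf("S%02d", 1:40)))
  # segment-like carriers: constant within the amplicon, as segmentation
  # would deliver
  X[20:30, 1:12] <- 1.5       # amplicon A, freq 0.3
  X[150:160, 13:28] <- 1.5    # amplicon B, freq 0.4
  thr <- data.frame(sample = colnames(X), gain_thr = 0.15, loss_thr = -0.15)
  sc <- gscores(X, thr, "gain")
  nq <- marker_null_and_q(sc, gistic_config(n_permutations = 300))
  reg <- significant_regions(sc, nq, pr, gistic_config(n_permutations = 300))
  expect_gte(nrow(reg), 2)
  expect_true(any(reg$peak_start <= pr$start[20] + 1e5 &
                    reg$peak_end >= pr$end[30] - 1e5))
  expect_true(any(reg$peak_start <= pr$start[150] + 1e5 &
                    reg$peak_end >= pr$end[160] - 1e5))
})

test_that("region means average segment means probe-weighted", {
  pr <- tiny_probes(20)
  X <- matrix(c(rep(0.7, 20), rep(0, 4), rep(1, 4), rep(0.5, 12)), 20, 2,
              dimnames = list(pr$probe, c("A", "B")))
  # region inside one constant block
  r1 <- region_mean_log2(list(chrom = "chr1", start = 1, end = 5e5), X, pr)
  expect_equal(unname(r1["A"]), 0.7)
  # region spanning 4 probes at 0 and 4 probes at 1
  r2 <- region_mean_log2(list(chrom = "chr1", start = 1, end = 8e5), X, pr)
  expect_equal(unname(r2["B"]), 0.5)
  # random regions equal the probe-weighted oracle
  set.seed(23)
  for (rep in 1:10) {
    lo <- sample(1:15, 1); hi <- sample(lo:20, 1)
    rr <- region_mean_log2(list(chrom = "chr1", start = pr$start[lo],
                                end = pr$end[hi]), X, pr)
    expect_equal(unname(rr), unname(colMeans(X[lo:hi, , drop = FALSE])))
  }
})

test_that("region-covariate association finds planted group differences", {
  pr <- tiny_probes(60)
  set.seed(3)
  n <- 30
  X <- matrix(rnorm(60 * n, 0, 0.05), 60, n,
              dimnames = list(pr$probe, sprintf("S%02d", 1:n)))
  md <- data.frame(sample = colnames(X),
                   ER = rep(c("pos", "neg"), each = 15))
  X[10:20, md$ER == "pos"] <- X[10:20, md$ER == "pos"] + 0.8
  regions <- data.frame(direction = "gain", chrom = "chr1",
                        wide_start = pr$start[c(10, 30, 40, 50)],
                        wide_end = pr$end[c(20, 35, 45, 55)])
  res <- region_covariate_association(regions, X, pr, md, "ER")
  expect_true(res$significant[1])
  expect_lte(sum(res$significant[-1]), 1)
  # identical constant group values: t = 0, p = 1
  Xc <- matrix(0.3, 60, n, dimnames = dimnames(X))
  resc <- region_covariate_association(regions, Xc, pr, md, "ER")
  expect_equal(resc$t, rep(0, 4))
  expect_equal(resc$p, rep(1, 4))
  # independent covariate: no significant region in most runs
  set.seed(8)
  hits <- vapply(1:20, function(i) {
    md2 <- data.frame(sample = colnames(X),
                      ER = sample(rep(c("pos", "neg"), each = 15)))
    Xr <- matrix(rnorm(60 * n, 0, 0.2), 60, n, dimnames = dimnames(X))
    sum(region_covariate_association(regions, Xr, pr, md2,
                                     "ER")$significant)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})
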