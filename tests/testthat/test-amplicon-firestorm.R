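test_that("SRO is the intersection of carrier runs containing the anchor", {
  # carriers with amplified runs [100, 500] and [300, 800], anchor at 400
  pr <- probe_set(sprintf("p%02d", 1:8), "chr1",
                  seq(1, 800, 100), seq(100, 800, 100))
  s1 <- rep(1L, 8); s1[1:5] <- 3L   # run 1..500
  s2 <- rep(1L, 8); s2[3:8] <- 3L   # run 201..800
  st <- make_states(cbind(s1, s2))
  r <- sro(st, pr, list(chrom = "chr1", start = 301, end = 400))
  expect_equal(r$start, 201)
  expect_equal(r$end, 500)
  expect_setequal(r$carriers, colnames(st))
  # single carrier: SRO equals that carrier's run
  st1 <- make_states(cbind(s1))
  r1 <- sro(st1, pr, list(chrom = "chr1", start = 301, end = 400))
  expect_equal(c(r1$start, r1$end), c(1, 500))
  # no carriers: warning and NULL
  stn <- make_states(cbind(rep(1L, 8)))
  expect_warning(rn <- sro(stn, pr, list(chrom = "chr1", start = 301,
                                         end = 400)), "no carriers")
  expect_null(rn)
})

test_that("SRO contains the anchor and matches the per-base oracle", {
  set.seed(55)
  pr <- tiny_probes(40, spacing = 1000)
  anchor <- list(chrom = "chr1", start = pr$start[20], end = pr$end[21])
  for (rep in 1:30) {
    ns <- sample(2:6, 1)
    st <- make_states(vapply(seq_len(ns), function(s) {
      v <- rep(1L, 40)
      lo <- sample(1:20, 1); hi <- sample(21:40, 1)
      v[lo:hi] <- 3L
      # random extra noise states away from the anchor
      v[sample(1:40, 5)] <- sample(0:2, 5, replace = TRUE)
      v[20:21] <- 3L
      v
    }, integer(40)))
    r <- sro(st, pr, anchor)
    o <- oracle_sro(st, pr, anchor)
    expect_equal(unname(c(r$start, r$end)), unname(o))
    expect_lte(r$start, anchor$start)
    expect_gte(r$end, anchor$end)
  }
})

test_that("interval lengths in kbp reproduce printed values", {
  expect_identical(interval_length_kbp(35074472, 35160391), 85.92)
  expect_identical(interval_length_kbp(35067680, 35851322), 783.64)
  expect_identical(interval_length_kbp(34979166, 35227087, decimals = 0), 248)
  expect_identical(interval_length_kbp(7, 7, decimals = 3), 0.001)
  expect_identical(interval_length_kbp(list(start = 1, end = 1000)), 1)
})

test_that("recurrent peaks respect the frequency threshold boundary", {
  pr <- tiny_probes(30)
  n <- 200
  mk_cohort <- function(k_carriers) {
    st <- matrix(1L, 30, n, dimnames = list(pr$probe, sprintf("S%03d", 1:n)))
    if (k_carriers > 0) st[10:14, seq_len(k_carriers)] <- 4L
    st
  }
  # 3/200 = 0.015 <= 0.02: no peak
  expect_equal(nrow(recurrent_peaks(mk_cohort(3), pr)), 0)
  # 5/200 = 0.025 > 0.02: one peak
  pk <- recurrent_peaks(mk_cohort(5), pr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_carriers, 5)
  expect_equal(pk$frequency, 0.025)
  # exactly 4/200 = 0.02 is not "> 2%"
  expect_equal(nrow(recurrent_peaks(mk_cohort(4), pr)), 0)
})

test_that("distinct planted amplicons yield distinct peaks with their carriers", {
  asm <- tiny_assembly(len = 3e7)
  cfg <- sim_config(60, assembly = asm, probe_spacing = 1e5, noise_sd = 0,
                    events = list(
                      event_focal_amp("chr1", 2e6 + 1, 3e6, amplitude = 1.6,
                                      frequency = 0.2),
                      event_focal_amp("chr1", 13e6 + 1, 14e6, amplitude = 1.6,
                                      frequency = 0.4)),
                    expression = NULL, seed = 14)
  co <- simulate_cohort(cfg)
  set.seed(14)
  seg <- filter_min_probes(cbs_segment(co$cn, co$probes,
                                       seg_config(n_permutations = 100)), 4)
  thr <- data.frame(sample = colnames(co$cn), gain_thr = 0.2,
                    loss_thr = -0.2)
  st <- call_states(seg, co$probes, thr, calling_config())
  pk <- recurrent_peaks(st, co$probes)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$members[[which(pk$start < 1e7)]],
                  co$truth$carriers[[1]])
  expect_setequal(pk$members[[which(pk$start > 1e7)]],
                  co$truth$carriers[[2]])
  # each peak contains its driver
  expect_lte(pk$start[1], 2e6 + 1); expect_gte(pk$end[1], 3e6)
  expect_lte(pk$start[2], 13e6 + 1); expect_gte(pk$end[2], 14e6)
})

test_that("co-amplification fractions follow both denominators", {
  a <- sprintf("S%02d", 1:5)
  b <- sprintf("S%02d", 4:13)   # overlap of 2, nA = 5, nB = 10
  expect_equal(coamp_fraction(a, b, "min"), 0.4)
  expect_equal(coamp_fraction(a, b, "row"), 0.4)
  expect_equal(coamp_fraction(b, a, "row"), 0.2)
  expect_equal(coamp_fraction(a, a, "min"), 1)
  expect_equal(coamp_fraction(a, a, "row"), 1)
  expect_equal(coamp_fraction(a, sprintf("X%02d", 1:4), "min"), 0)
  expect_error(coamp_fraction(a, character(0)), "zero carriers")
  # min-mode value equals the max of the two row-mode values
  set.seed(6)
  for (rep in 1:20) {
    pool <- sprintf("S%03d", 1:50)
    x <- sample(pool, sample(3:20, 1))
    y <- sample(pool, sample(3:20, 1))
    expect_equal(coamp_fraction(x, y, "min"),
                 max(coamp_fraction(x, y, "row"),
                     coamp_fraction(y, x, "row")))
  }
})

test_that("mutual exclusivity test matches Fisher and flags Haldane", {
  samples <- sprintf("S%02d", 1:20)
  res <- mutual_exclusivity_test(samples[1:10], samples[11:20], samples)
  expect_lt(res$p_value, 0.01)
  expect_true(res$haldane)
  expect_true(is.finite(res$odds_ratio))
  expect_lt(res$odds_ratio, 1)    # disjoint: odds ratio below 1
  # independent carriers: the exact test is valid (never anti-conservative)
  # and its discrete p-values stochastically dominate the uniform
  set.seed(123)
  ps <- vapply(1:300, function(i) {
    big <- sprintf("S%03d", 1:60)
    a <- big[runif(60) < 0.4]
    b <- big[runif(60) < 0.4]
    if (!length(a) || !length(b)) return(NA_real_)
    mutual_exclusivity_test(a, b, big)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  for (q in c(0.01, 0.05, 0.2)) {
    expect_lte(mean(ps <= q), q + 2.5 * sqrt(q * (1 - q) / length(ps)))
  }
  expect_gt(median(ps), 0.2)   # not degenerate at small values
  # degenerate margins
  expect_warning(r0 <- mutual_exclusivity_test(character(0), samples[1:3],
                                               samples), "degenerate")
  expect_equal(r0$p_value, 1)
})

test_that("HER2/TOP2A status follows the threshold rules", {
  pr <- tiny_probes(20)
  her2 <- list(chrom = "chr1", start = 4e5 + 1, end = 5e5)      # probe 5
  top2a <- list(chrom = "chr1", start = 12e5 + 1, end = 13e5)   # probe 13
  mk <- function(h, t, sample) {
    data.frame(sample = sample, chrom = "chr1",
               start = c(1, 1001), end = c(1000, 2000),
               probe_first = c(1, 11), probe_last = c(10, 20),
               n_probes = c(10, 10), seg_mean = c(h, t))
  }
  seg <- rbind(mk(1.2, 0.9, "S1"), mk(1.2, -0.5, "S2"), mk(1.2, 0.1, "S3"),
               mk(0.2, 0.9, "S4"))
  thr <- data.frame(sample = paste0("S", 1:4), gain_thr = 0.2,
                    loss_thr = -0.2)
  st <- her2_top2a_status(seg, pr, her2, top2a, thr)
  expect_equal(st$status, c("coamplified", "top2a_deleted", "top2a_neutral",
                            NA))
  # TOP2A-loss percentage arithmetic on printed counts
  expect_equal(100 * 36 / 200, 18)
})

test_that("firestorm detection enforces every rule clause", {
  asm <- tiny_assembly()              # q arm 9e6..2e7, 110 probes
  pr <- make_probe_grid(asm, 1e5)
  qrows <- which(pr$center > asm$cen_end[1])
  base <- rep(1L, nrow(pr))
  put_peaks <- function(v, starts, width) {
    for (s in starts) v[qrows[s:(s + width - 1)]] <- 4L
    v
  }
  # 3 peaks of 5 probes, tight spacing: one call
  v <- put_peaks(base, c(1, 11, 21), 5)
  st <- make_states(cbind(v))
  fs <- detect_firestorms(st, pr, asm)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$arm, "q")
  expect_equal(fs$n_peaks, 3)
  # a 3-probe peak does not qualify (needs > 3 probes)
  v2 <- put_peaks(base, c(1, 11), 5)
  v2 <- put_peaks(v2, 21, 3)
  expect_equal(nrow(detect_firestorms(make_states(cbind(v2)), pr, asm)), 0)
  # peaks not separated by a sub-amplification probe: no call
  v3 <- put_peaks(base, c(1, 11, 21), 5)
  v3[qrows[6:10]] <- 3L    # amplification-level plateau between peaks 1 and 2
  expect_equal(nrow(detect_firestorms(make_states(cbind(v3)), pr, asm)), 0)
  # spacing beyond half the arm length: no call
  v4 <- put_peaks(base, c(1, 11, 100), 6)
  expect_equal(nrow(detect_firestorms(make_states(cbind(v4)), pr, asm)), 0)
  # adding a qualifying peak never removes the call (monotonicity)
  v5 <- put_peaks(v, 31, 5)
  expect_equal(nrow(detect_firestorms(make_states(cbind(v5)), pr, asm)), 1)
})

test_that("random planted layouts agree with the clause-by-clause oracle", {
  asm <- tiny_assembly()
  pr <- make_probe_grid(asm, 1e5)
  at <- arm_table(asm)
  qlen <- at$arm_length[at$arm == "q"]
  qrows <- which(pr$center > asm$cen_end[1])
  set.seed(77)
  n_agree <- 0
  n_cases <- 100
  for (rep in seq_len(n_cases)) {
    v <- rep(1L, nrow(pr))
    n_peaks <- sample(2:4, 1)
    width <- sample(3:5, 1)
    gap <- sample(c(2, 20, 45, 60), 1)
    at_pos <- 1
    for (k in seq_len(n_peaks)) {
      if (at_pos + width - 1 > length(qrows)) break
      v[qrows[at_pos:(at_pos + width - 1)]] <- 4L
      at_pos <- at_pos + width + gap
    }
    # occasionally fill a gap with amplification-level probes
    if (runif(1) < 0.3 && n_peaks >= 2 && width + gap < length(qrows)) {
      v[qrows[(width + 1):(width + gap)]] <- 3L
    }
    st <- make_states(cbind(v))
    got <- any(detect_firestorms(st, pr, asm)$arm == "q")
    want <- oracle_firestorm_arm(v[qrows], pr$start[qrows], pr$end[qrows],
                                 qlen)
    n_agree <- n_agree + identical(got, isTRUE(want))
  }
  expect_equal(n_agree, n_cases)
})
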