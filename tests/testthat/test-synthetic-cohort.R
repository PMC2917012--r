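test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(6, assembly = tiny_assembly(n_chrom = 2),
                    probe_spacing = 5e5, noise_sd = 0.2,
                    events = list(event_focal_amp("chr1", 5e6, 7e6,
                                                  frequency = 0.5)),
                    expression = expr_config(n_genes = 50), seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cn, b$cn)
  expect_identical(a$expression$expr, b$expression$expr)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("noise-free focal amplicon at frequency 1 hits exactly the driver probes", {
  asm <- tiny_assembly()
  cfg <- sim_config(5, assembly = asm, probe_spacing = 1e5, noise_sd = 0,
                    events = list(event_focal_amp("chr1", 5e6 + 1, 6e6,
                                                  amplitude = 1.5,
                                                  frequency = 1,
                                                  ext_mean = 0)),
                    expression = NULL, seed = 2)
  co <- simulate_cohort(cfg)
  inside <- co$probes$center >= 5e6 + 1 & co$probes$center <= 6e6
  for (s in 1:5) {
    expect_true(all(co$cn[inside, s] == 1.5))
    expect_true(all(co$cn[!inside, s] == 0))
  }
  expect_true(all(co$truth$events$start == 5e6 + 1))
  expect_true(all(co$truth$events$end == 6e6))
})

test_that("carrier draws follow the event frequency", {
  freq <- 0.3; n <- 200; n_seeds <- 50
  fracs <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n, assembly = tiny_assembly(), probe_spacing = 2e6,
                      noise_sd = 0,
                      events = list(event_focal_amp("chr1", 1e6, 3e6,
                                                    frequency = freq)),
                      expression = NULL, seed = s)
    co <- simulate_cohort(cfg)
    length(co$truth$carriers[[1]]) / n
  }, numeric(1))
  se <- sqrt(freq * (1 - freq) / (n * n_seeds))
  expect_lt(abs(mean(fracs) - freq), 3 * se)
})

test_that("realized focal intervals contain the driver and intersect to it", {
  set.seed(31)
  asm <- tiny_assembly()
  pr <- make_probe_grid(asm, 1e5)
  driver <- c(9e6 + 1, 10e6)
  ints <- t(vapply(1:40, function(i) {
    r <- plant_focal_amp(numeric(nrow(pr)), pr, "chr1", driver[1], driver[2],
                         1.5, ext_mean = 8e5, chrom_length = asm$length[1])
    r$interval
  }, numeric(2)))
  expect_true(all(ints[, 1] <= driver[1] & ints[, 2] >= driver[2]))
  # intersection oracle: [max starts, min ends] approaches the driver
  expect_gte(max(ints[, 1]), driver[1] - 2e5)
  expect_lte(min(ints[, 2]), driver[2] + 2e5)
  # doubling the extension increases mean realized length (Monte Carlo)
  len1 <- mean(ints[, 2] - ints[, 1])
  ints2 <- t(vapply(1:40, function(i) {
    plant_focal_amp(numeric(nrow(pr)), pr, "chr1", driver[1], driver[2],
                    1.5, ext_mean = 1.6e6, chrom_length = asm$length[1])$interval
  }, numeric(2)))
  expect_gt(mean(ints2[, 2] - ints2[, 1]), len1)
  # extensions never leave the chromosome
  expect_true(all(ints2[, 1] >= 1 & ints2[, 2] <= asm$length[1]))
})

test_that("firestorm planting realizes the requested layout or errors", {
  asm <- tiny_assembly()
  pr <- make_probe_grid(asm, 1e5)
  r <- plant_firestorm(numeric(nrow(pr)), pr, "chr1", "q", asm,
                       n_peaks = 3, amplitude = 1.5, peak_width_probes = 5,
                       gap_probes = 10)
  expect_equal(nrow(r$peaks), 3)
  # peaks disjoint, separated by baseline
  expect_true(all(diff(r$peaks$probe_first) > 5))
  for (k in 1:3) {
    run <- r$peaks$probe_first[k]:r$peaks$probe_last[k]
    expect_true(all(r$values[run] == 1.5))
  }
  gaps <- setdiff(min(r$peaks$probe_first):max(r$peaks$probe_last),
                  unlist(lapply(1:3, function(k)
                    r$peaks$probe_first[k]:r$peaks$probe_last[k])))
  expect_true(all(r$values[gaps] == 0))
  expect_error(
    plant_firestorm(numeric(nrow(pr)), pr, "chr1", "q", asm, n_peaks = 50,
                    amplitude = 1.5, peak_width_probes = 5, gap_probes = 10),
    "infeasible on chr1q")
})

test_that("null profiles are Gaussian with the configured SD", {
  cfg <- sim_config(30, assembly = tiny_assembly(n_chrom = 2),
                    probe_spacing = 1e5, noise_sd = 0.3,
                    expression = NULL, seed = 77)
  co <- simulate_cohort(cfg)
  v <- as.vector(co$cn)
  n <- length(v)
  expect_gte(n, 1e4)
  expect_lt(abs(mean(v)), 4 * 0.3 / sqrt(n))
  expect_lt(abs(sd(v) - 0.3), 4 * 0.3 / sqrt(2 * n))
})

test_that("expression carries the configured dosage component", {
  asm <- tiny_assembly()
  # beta = 1, no noise: r = 1 for responsive genes on variable probes
  cfg <- sim_config(30, assembly = asm, probe_spacing = 1e6, noise_sd = 0.1,
                    events = list(event_broad("chr1", "both",
                                              amplitude = 1, frequency = 0.5)),
                    expression = expr_config(n_genes = 60,
                                             frac_responsive = 0.5,
                                             beta = 1, noise_sd = 0),
                    seed = 12)
  co <- simulate_cohort(cfg)
  g <- co$expression$genes
  for (i in which(g$responsive)[1:5]) {
    r <- cor(co$expression$expr[i, ], co$cn[g$probe_row[i], ])
    expect_equal(r, 1, tolerance = 1e-12)
  }
  # beta = 0 for all genes: expression independent of copy number
  cfg0 <- sim_config(30, assembly = asm, probe_spacing = 1e6, noise_sd = 0.1,
                     events = list(event_broad("chr1", "both",
                                               amplitude = 1, frequency = 0.5)),
                     expression = expr_config(n_genes = 60,
                                              frac_responsive = 0,
                                              noise_sd = 0.5),
                     seed = 12)
  co0 <- simulate_cohort(cfg0)
  rs <- vapply(seq_len(60), function(i)
    cor(co0$expression$expr[i, ], co0$cn[co0$expression$genes$probe_row[i], ]),
    numeric(1))
  expect_lt(mean(abs(rs)), 0.25)
})

test_that("observed dosage correlation matches the attenuation closed form", {
  # r = beta * sd_cn / sqrt(beta^2 sd_cn^2 + sd_eps^2), Monte Carlo at n = 100
  asm <- tiny_assembly()
  beta <- 0.5; eps <- 0.5
  cfg <- sim_config(100, assembly = asm, probe_spacing = 1e6, noise_sd = 0,
                    events = list(event_broad("chr1", "both", amplitude = 1,
                                              frequency = 0.5)),
                    expression = expr_config(n_genes = 200,
                                             frac_responsive = 1,
                                             beta = beta, noise_sd = eps),
                    seed = 8)
  co <- simulate_cohort(cfg)
  g <- co$expression$genes
  on_event <- g$chrom == "chr1"
  rs <- vapply(which(on_event), function(i) {
    cn <- co$cn[g$probe_row[i], ]
    cor(co$expression$expr[i, ], cn)
  }, numeric(1))
  sd_cn <- 0.5  # binary 0/1 at frequency 0.5
  expected <- beta * sd_cn / sqrt(beta^2 * sd_cn^2 + eps^2)
  expect_lt(abs(mean(rs) - expected), 0.05)
})

test_that("the truth ledger replays every planted interval", {
  cfg <- sim_config(8, assembly = tiny_assembly(), probe_spacing = 1e5,
                    noise_sd = 0,
                    events = list(event_focal_amp("chr1", 2e6 + 1, 3e6,
                                                  amplitude = 2,
                                                  frequency = 1)),
                    expression = NULL, seed = 21)
  co <- simulate_cohort(cfg)
  ev <- co$truth$events
  for (r in seq_len(nrow(ev))) {
    inside <- co$probes$center >= ev$start[r] & co$probes$center <= ev$end[r]
    expect_true(all(co$cn[inside, ev$sample[r]] == ev$amplitude[r]))
  }
})

test_that("her2 amplicon variants produce the three TOP2A classes", {
  asm <- tiny_assembly()
  mk <- function(variant) {
    cfg <- sim_config(4, assembly = asm, probe_spacing = 1e5, noise_sd = 0,
                      events = list(event_her2_amplicon(
                        "chr1", 15e6 + 1, 15.2e6, variant = variant,
                        amplitude = 1.5, frequency = 1)),
                      expression = NULL, seed = 3)
    simulate_cohort(cfg)
  }
  her2_probes <- function(co) co$probes$center >= 15e6 + 1 &
    co$probes$center <= 15.2e6
  top2a_start <- 15.2e6 + 7e5 + 1
  top2a_probes <- function(co) co$probes$center >= top2a_start &
    co$probes$center <= top2a_start + 1e5 - 1
  co1 <- mk("coamplified")
  expect_true(all(co1$cn[her2_probes(co1), 1] == 1.5))
  expect_true(all(co1$cn[top2a_probes(co1), 1] == 1.5))
  co2 <- mk("top2a_deleted")
  expect_true(all(co2$cn[her2_probes(co2), 1] == 1.5))
  expect_true(all(co2$cn[top2a_probes(co2), 1] == -0.8))
  co3 <- mk("top2a_neutral")
  expect_true(all(co3$cn[her2_probes(co3), 1] == 1.5))
  expect_true(all(co3$cn[top2a_probes(co3), 1] == 0))
})
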