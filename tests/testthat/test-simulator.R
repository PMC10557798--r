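test_that("Arrhenius rates follow the planted free-energy sums with the stated signs", {
  cfg <- sim_config(seed = 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  set.seed(1)
  g <- sample(bases, 50, replace = TRUE)
  t <- comp[g]   # fully complementary: every window sums to 5 x (-1)
  r <- arrhenius_rates(cfg, g, t)
  # forward transitions (alpha < beta): k = k0 exp(+5); backward: k0 exp(-5)
  expect_equal(unname(r["k01"]), 0.01 * exp(5), tolerance = 1e-12)
  expect_equal(unname(r["k12"]), 0.01 * exp(5), tolerance = 1e-12)
  expect_equal(unname(r["k23"]), 0.01 * exp(5), tolerance = 1e-12)
  expect_equal(unname(r["k10"]), 0.01 * exp(-5), tolerance = 1e-12)
  expect_equal(unname(r["k21"]), 0.01 * exp(-5), tolerance = 1e-12)
  expect_equal(unname(r["k32"]), 0.01 * exp(-5), tolerance = 1e-12)
  # the cut step runs 3 -> 0, so the stated index rule gives it the + sign
  expect_equal(unname(r["k30"]), 0.01 * exp(-5), tolerance = 1e-12)
  # mismatch table: complementary pairs fixed at -1, mismatches from the set
  expect_true(all(cfg$dG_table[, "match"] == -1))
  expect_true(all(cfg$dG_table[, 2:4] %in% c(-0.1, 0.1, 1)))
})

test_that("default windows tile the active region disjointly, one per rate", {
  cfg <- sim_config()
  expect_identical(cfg$windows$start, 5L + 5L * (0:6))
  expect_identical(cfg$windows$end, 10L + 5L * (0:6))
  expect_identical(cfg$windows$symbol, cas9_scheme()$edges$symbol)
  idx <- unlist(Map(function(s, e) s:(e - 1), cfg$windows$start,
                    cfg$windows$end))
  expect_identical(sort(idx), 5:39)          # [5, 40), no overlap
  expect_error(sim_config(active_region = c(5, 41)), "must equal")
})

test_that("labels depend only on the active region and are positive and reproducible", {
  cfg <- sim_config(seed = 2)
  d <- simulate_invitro(cfg, 50, seed = 5)
  expect_true(all(d$cleavage_rate > 0 & is.finite(d$cleavage_rate)))
  # identical draw under the same seed, bitwise
  d2 <- simulate_invitro(cfg, 50, seed = 5)
  expect_identical(d, d2)
  # flanks (outside [5,40)) do not change rates or label
  g <- strsplit(d$guide_seq[1], "")[[1]]
  t <- strsplit(d$target_seq[1], "")[[1]]
  g[c(1:5, 41:50)] <- "A"; t[c(1:5, 41:50)] <- "A"
  r1 <- arrhenius_rates(cfg, d$guide_seq[1], d$target_seq[1])
  r2 <- arrhenius_rates(cfg, g, t)
  expect_identical(r1, r2)
  # rates in the table regenerate exactly from (config, sequence)
  expect_equal(unlist(d[3, cfg$windows$symbol]),
               arrhenius_rates(cfg, d$guide_seq[3], d$target_seq[3]),
               tolerance = 1e-15, ignore_attr = TRUE)
  # label is the slow mode of the depleting-reservoir matrix of those rates
  r3 <- unlist(d[3, cfg$windows$symbol])
  expect_equal(d$cleavage_rate[3], slow_eigen_rate(cfg$scheme, r3),
               tolerance = 1e-12)
  # log labels span multiple decades under the default free-energy spread
  d_big <- simulate_invitro(cfg, 400, seed = 6)
  expect_gt(diff(range(log10(d_big$cleavage_rate))), 2)
})

test_that("in vivo simulator plants a recoverable context effect with fixed seed", {
  pk <- planted_invivo_kinn(seed = 5)
  s1 <- simulate_invivo(pk, n = 300, seed = 3)
  s2 <- simulate_invivo(pk, n = 300, seed = 3)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$X, s2$X)
  expect_true(all(s1$table$label %in% c(0, 1)))
  expect_identical(dim(s1$X), c(300L, 25L, 13L))
  # noiseless, zero-context limit: labels rank exactly by the planted rate
  s0 <- simulate_invivo(pk, n = 600, seed = 4,
                        context_effect = list(per_G = 0, noise_sd = 0),
                        slope = 60)
  expect_gt(auroc(s0$table$log_rate, s0$table$label), 0.98)
})
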