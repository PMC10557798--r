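test_that("the anchor function places rates uniformly along the input", {
  # four-state scheme, 20-bp input: the canonical worked placements
  expect_identical(anchor_position("k01", 4, 20), 5L)
  expect_identical(anchor_position("k12", 4, 20), 10L)
  expect_identical(anchor_position("k23", 4, 20), 15L)
  # backward rates inherit their forward partner's anchor
  expect_identical(anchor_position("k10", 4, 20), anchor_position("k01", 4, 20))
  expect_identical(anchor_position("k32", 4, 20), anchor_position("k23", 4, 20))
  # the cycle-closing cut is anchored by its origin state
  expect_identical(anchor_position("k30", 4, 20), 20L)
  expect_error(anchor_position("k45", 4, 20), "does not belong")
  expect_error(anchor_position("k01", 4, 3), "at least")
})

test_that("architecture sampling respects the prior and produces valid specs", {
  sc <- cas9_scheme()
  # w = 0: start is a point mass at the anchor
  pr0 <- architecture_prior(sc, input_length = 50, w = 0)
  set.seed(1)
  for (i in 1:5) {
    a <- sample_architecture(pr0)
    expect_identical(a$windows$start,
                     vapply(a$windows$symbol,
                            function(s) min(anchor_position(s, 4, 50), 49L),
                            1L, USE.NAMES = FALSE))
  }
  # sampled specs always satisfy the window invariants
  pr <- architecture_prior(sc, input_length = 50, w = 10)
  set.seed(2)
  for (i in 1:200) {
    a <- sample_architecture(pr)
    w <- a$windows
    expect_true(all(w$start >= 0 & w$start < w$end & w$end <= 50))
    expect_true(all(w$kernel >= 1 & w$kernel <= w$end - w$start))
  }
  # empirical start frequencies match the categorical prior (chi-squared GOF)
  set.seed(3)
  draws <- vapply(1:4000, function(i)
    sample_architecture(pr)$windows$start[3], 1L)   # k12 start
  sup <- pr$per_edge[["k12"]]$start$support
  obs <- table(factor(draws, levels = sup))
  gof <- suppressWarnings(stats::chisq.test(obs,
                                            p = rep(1 / length(sup),
                                                    length(sup))))
  expect_gt(gof$p.value, 0.01)
})

test_that("posterior updates add survivor pseudo-counts and stay normalized", {
  sc <- cas9_scheme()
  pr <- architecture_prior(sc, input_length = 50, w = 10)
  set.seed(4)
  survivors <- replicate(3, sample_architecture(pr), simplify = FALSE)
  post <- update_posterior(pr, survivors)
  for (s in names(post$per_edge)) {
    for (slot in c("start", "len", "kernel")) {
      p <- kinn:::prior_probs(post$per_edge[[s]][[slot]])
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
  # a start position shared by every survivor strictly gains probability
  shared <- attr(survivors[[1]], "choices")$start[1]
  for (k in 2:3) attr(survivors[[k]], "choices")$start[1] <- shared
  post2 <- update_posterior(pr, survivors)
  i <- match(shared, pr$per_edge[[1]]$start$support)
  expect_gt(kinn:::prior_probs(post2$per_edge[[1]]$start)[i],
            kinn:::prior_probs(pr$per_edge[[1]]$start)[i])
})

test_that("the search loop is reproducible with a monotone best-so-far curve", {
  fx <- invitro_fixture(n = 260, seed = 31)
  tr <- list(x = fx$X[1:200, , ], y = fx$data$cleavage_rate[1:200])
  va <- list(x = fx$X[201:260, , ], y = fx$data$cleavage_rate[201:260])
  pr <- architecture_prior(fx$cfg$scheme, input_length = 50, w = 10)
  cfg <- train_config(epochs = 10, lr = 0.1, patience = 4)
  r1 <- kinn_search(pr, tr, va, generations = 3, pop = 3, config = cfg,
                    seed = 5)
  r2 <- kinn_search(pr, tr, va, generations = 3, pop = 3, config = cfg,
                    seed = 5)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$evaluations$fitness, r2$evaluations$fitness)
  expect_true(all(diff(r1$history$best_so_far) >= 0))
  expect_gte(r1$best_fitness, r1$history$max_fitness[1])
  expect_s3_class(r1$best_model, "kinn_model")
})

test_that("all-equal fitness falls back to the top half and still updates cleanly", {
  fx <- invitro_fixture(n = 80, seed = 32)
  y <- rep(0.01, 80)    # constant labels: every fitness is exactly 0
  pr <- architecture_prior(fx$cfg$scheme, input_length = 50, w = 10)
  suppressWarnings(
    r <- kinn_search(pr, list(x = fx$X[1:60, , ], y = y[1:60]),
                     list(x = fx$X[61:80, , ], y = y[61:80]),
                     generations = 2, pop = 4,
                     config = train_config(epochs = 3), seed = 6))
  expect_true(all(r$evaluations$fitness == 0))
  for (s in names(r$posterior$per_edge))
    expect_equal(sum(kinn:::prior_probs(r$posterior$per_edge[[s]]$start)), 1,
                 tolerance = 1e-12)
  # pseudo-counts were added for exactly top-half survivors per generation
  total_alpha <- sum(r$posterior$per_edge[[1]]$start$alpha)
  base_alpha <- sum(pr$per_edge[[1]]$start$alpha)
  expect_identical(total_alpha - base_alpha, 2 * 2)   # 2 gens x ceil(4/2)
})
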