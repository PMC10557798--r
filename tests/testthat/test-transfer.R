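test_that("modifiers combine with frozen log rates exponentially", {
  kap <- c(k01 = log(2), k10 = 0, k30 = log(5))
  expect_equal(combine_rates(kap, rep(0, 3)), exp(kap))
  d <- c(log(2), 0, 0)
  kp <- combine_rates(kap, d)
  expect_equal(unname(kp[1]), 4)
  expect_equal(unname(kp[2:3]), unname(exp(kap[2:3])))
  expect_error(combine_rates(kap, 0), "equal length")
  # algebraic path equivalence: modified rates -> KA equals direct KA
  sc <- cas9_scheme()
  set.seed(1)
  kap7 <- log(random_rates(sc)); del7 <- rnorm(7, 0, 0.5)
  expect_equal(steady_state_ka(sc, combine_rates(kap7, del7)),
               steady_state_ka(sc, exp(kap7 + del7)), tolerance = 1e-12)
})

test_that("an untrained transfer model ranks inputs exactly like its frozen KINN", {
  pk <- planted_invivo_kinn(seed = 5)
  sim <- simulate_invivo(pk, n = 120, seed = 2)
  tm <- transfer_model(pk, backbone_spec(conv1 = "k3"), seed = 3)
  # the modifier head is zero-initialized, so delta = 0 at construction
  p <- predict_proba(tm, sim$X)
  expect_true(all(p > 0 & p < 1))
  base <- kinn_forward(pk$architecture, pk$parameters, sim$X)$y
  expect_identical(order(p), order(base))
  # single-record matrix input works
  expect_length(predict_proba(tm, sim$X[1, , ]), 1)
  expect_error(predict_proba(tm, matrix(0, 10, 13)), "25 x 13")
})

test_that("transfer training improves on planted context, keeps the KINN frozen, and reproduces", {
  pk <- planted_invivo_kinn(seed = 5)
  sim <- simulate_invivo(pk, n = 900, seed = 7)
  sp <- split_by_guide(sim$table$guide_id, 0.25, seed = 1)
  tr <- list(X = sim$X[sp$train, , ], y = sim$table$label[sp$train])
  va <- list(X = sim$X[sp$validation, , ], y = sim$table$label[sp$validation])
  fp0 <- param_fingerprint(pk$parameters)
  tm <- transfer_model(pk, backbone_spec(conv1 = "k3", dropout = 0.1),
                       seed = 4)
  cfg <- transfer_config(epochs = 4, patience = 4, seed = 11)
  t1 <- fit_transfer(tm, tr, va, cfg)
  t2 <- fit_transfer(tm, tr, va, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(param_fingerprint(t1$frozen$parameters), fp0)
  expect_identical(param_fingerprint(pk$parameters), fp0)
  expect_true(all(diff(range(t1$history$val_ap)) >= 0))
  expect_error(fit_transfer(tm, list(X = tr$X, y = rep(0, length(tr$y))),
                            va, cfg),
               "single-class")
})

test_that("a singleton model space returns its only candidate with unit frequencies", {
  pk <- planted_invivo_kinn(seed = 5)
  sim <- simulate_invivo(pk, n = 400, seed = 8)
  sp <- split_by_guide(sim$table$guide_id, 0.25, seed = 2)
  tr <- list(X = sim$X[sp$train, , ], y = sim$table$label[sp$train])
  va <- list(X = sim$X[sp$validation, , ], y = sim$table$label[sp$validation])
  space <- model_space(list(pk), conv1 = "k1", conv2 = "identity",
                       dropout = 0.1, recurrent = "identity",
                       flatten = "plain")
  sel <- select_model(space, tr, va, budget = 2,
                      config = transfer_config(epochs = 2, patience = 2),
                      seed = 3, top_n = 2)
  expect_s3_class(sel$best_model, "transfer_model")
  for (sl in names(sel$frequencies))
    expect_equal(max(as.numeric(sel$frequencies[[sl]])), 1)
  expect_error(select_model(space, tr, va, budget = 0), "at least 1")
  # ensemble mean prediction never has worse log-loss than the worst member
  logloss <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  pe <- ensemble_predict(sel$ensemble, va$X)
  member_ll <- vapply(sel$ensemble,
                      function(m) logloss(predict_proba(m, va$X), va$y), 0)
  expect_lte(logloss(pe, va$y), max(member_ll) + 1e-12)
})

test_that("transfer checkpoints round-trip through JSON", {
  pk <- planted_invivo_kinn(seed = 5)
  sim <- simulate_invivo(pk, n = 150, seed = 9)
  tm <- transfer_model(pk, backbone_spec(conv1 = "k3", flatten = "attention"),
                       seed = 6)
  path <- tempfile(fileext = ".json")
  save_transfer(tm, path)
  tm2 <- load_transfer(path)
  expect_equal(predict_proba(tm2, sim$X[1:20, , ]),
               predict_proba(tm, sim$X[1:20, , ]), tolerance = 1e-12)
  unlink(path)
})
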