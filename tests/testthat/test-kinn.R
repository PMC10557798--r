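test_that("log-rate heads are the promised affine maps of their windows", {
  fx <- invitro_fixture(n = 20)
  arch <- fx$arch
  p <- kinn_init(arch, labels = fx$data$cleavage_rate, seed = 1)
  # zero weights -> log rate is the bias, for every input
  p0 <- p
  for (e in seq_along(p0$kernels)) p0$kernels[[e]]$W[] <- 0
  lr <- log_rates(arch, p0, fx$X)
  for (e in seq_along(p0$kernels))
    expect_equal(unname(lr[, e]), rep(p0$kernels[[e]]$b, 20))
  # d = 1: weighted sum of per-position channel contributions (naive loop oracle)
  lr1 <- log_rates(arch, p, fx$X[1, , ])
  for (e in seq_along(p$kernels)) {
    w <- arch$windows[e, ]
    acc <- p$kernels[[e]]$b
    for (pos in (w$start + 1):w$end)
      acc <- acc + sum(fx$X[1, pos, ] * p$kernels[[e]]$W[1, ])
    expect_equal(unname(lr1[e]), acc, tolerance = 1e-12)
  }
  # d = j - i: the convolution collapses to a fully connected layer
  win_fc <- arch$windows
  win_fc$kernel <- win_fc$end - win_fc$start
  arch_fc <- kinn_architecture(fx$cfg$scheme, win_fc, fx$cfg$L, 4L)
  pfc <- kinn_init(arch_fc, seed = 2)
  lr_fc <- log_rates(arch_fc, pfc, fx$X[1, , ])
  for (e in seq_along(pfc$kernels)) {
    w <- arch_fc$windows[e, ]
    flat <- as.numeric(fx$X[1, (w$start + 1):w$end, ])  # column-major d x C
    wts <- as.numeric(pfc$kernels[[e]]$W)
    expect_equal(unname(lr_fc[e]), sum(flat * wts) + pfc$kernels[[e]]$b,
                 tolerance = 1e-12)
  }
})

test_that("the KA layer reproduces the exact King-Altman steady state", {
  sc <- cas9_scheme()
  dg <- enumerate_ka_diagrams(sc)
  # equal log-rates: occupancies proportional to per-state diagram counts
  s <- ka_layer(dg, rep(0.7, 7))
  counts <- tabulate(dg$terminal + 1L, 4)
  expect_equal(unname(s), counts / sum(counts), tolerance = 1e-12)
  # 2-state closed form
  two <- kinetic_scheme(2, c("k01", "k10"))
  expect_equal(unname(ka_layer(enumerate_ka_diagrams(two), c(log(2), 0))),
               c(1 / 3, 2 / 3), tolerance = 1e-12)
  # random rates: identical to steady_state_ka
  set.seed(12)
  for (i in 1:10) {
    r <- random_rates(sc)
    expect_equal(ka_layer(dg, log(r)), steady_state_ka(sc, r, dg),
                 tolerance = 1e-9)
  }
})

test_that("prediction with the identity head is the raw King-Altman activity", {
  fx <- invitro_fixture(n = 10)
  p <- kinn_init(fx$arch, labels = fx$data$cleavage_rate, seed = 3)
  pred <- kinn_forward(fx$arch, p, fx$X)$y
  for (i in c(1, 5, 10)) {
    r <- extract_rates(list(architecture = fx$arch, parameters = p),
                       fx$X[i, , ])
    s <- steady_state_ka(fx$cfg$scheme, r)
    expect_equal(pred[i], activity(fx$cfg$scheme, r, s), tolerance = 1e-10)
    expect_equal(sum(s), 1, tolerance = 1e-12)
  }
  # determinism: identical encodings give identical predictions
  expect_identical(pred[1], kinn_forward(fx$arch, p, fx$X[1, , ])$y)
})

test_that("rates are local to their windows", {
  fx <- invitro_fixture(n = 2)
  p <- kinn_init(fx$arch, seed = 4)
  x1 <- fx$X[1, , ]
  x2 <- x1
  x2[1:5, ] <- fx$X[2, 1:5, ]     # perturb only outside every window
  x2[41:50, ] <- fx$X[2, 41:50, ]
  expect_identical(log_rates(fx$arch, p, x1), log_rates(fx$arch, p, x2))
})

test_that("analytic gradients match central finite differences for both heads", {
  fx <- invitro_fixture(n = 4)
  set.seed(21)
  for (head in c("ka_steady_state", "eigen_rate")) {
    for (rep in 1:3) {
      win <- data.frame(symbol = fx$cfg$windows$symbol,
                        start = sample(0:30, 7, replace = TRUE))
      win$end <- win$start + sample(2:5, 7, replace = TRUE)
      win$kernel <- pmin(sample(1:2, 7, replace = TRUE),
                         win$end - win$start)
      arch <- kinn_architecture(fx$cfg$scheme, win, fx$cfg$L, 4L,
                                output_head = head,
                                link = kinn_link(hidden = 2,
                                                 act_nu = "softplus"))
      p <- kinn_init(arch, labels = 0.01, init_sd = 0.3,
                     seed = 100 + rep)
      x <- fx$X[sample(4, 1), , ]
      g <- kinn_predict_gradient(arch, p, x)
      flat <- kinn:::params_pack(p)
      h <- 1e-5
      fd <- vapply(seq_along(flat), function(i) {
        fp <- flat; fp[i] <- fp[i] + h
        fm <- flat; fm[i] <- fm[i] - h
        (kinn_forward(arch, kinn:::params_unpack(fp, p), x)$y -
           kinn_forward(arch, kinn:::params_unpack(fm, p), x)$y) / (2 * h)
      }, 0)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), abs(g), 1e-8)), 1e-4)
    }
  }
})

test_that("training is reproducible and recovers a planted model", {
  fx <- invitro_fixture(n = 500, seed = 77)
  tr <- list(x = fx$X[1:400, , ], y = fx$data$cleavage_rate[1:400])
  va <- list(x = fx$X[401:500, , ], y = fx$data$cleavage_rate[401:500])
  cfg <- train_config(epochs = 120, lr = 0.08, seed = 9, patience = 20)
  m1 <- kinn_fit(fx$arch, tr$x, tr$y, validation = va, config = cfg)
  m2 <- kinn_fit(fx$arch, tr$x, tr$y, validation = va, config = cfg)
  expect_identical(m1$history, m2$history)      # bitwise, same seed
  expect_gt(max(m1$history$val_pearson), 0.8)   # small-n sanity recovery
  # residuals/coef/summary surface
  expect_length(residuals(m1), 400)
  expect_true(all(is.finite(coef(m1))))
  expect_output(print(summary(m1)), "KINN fit")
})

test_that("degenerate constant labels yield zero fitness with a warning", {
  fx <- invitro_fixture(n = 60)
  y <- rep(0.02, 60)
  expect_warning(
    res <- evaluate_fitness(fx$arch,
                            list(x = fx$X[1:40, , ], y = y[1:40]),
                            list(x = fx$X[41:60, , ], y = y[41:60]),
                            train_config(epochs = 5)),
    "constant|Pearson")
  expect_equal(res$fitness, 0)
})

test_that("log-loss refuses nonpositive labels", {
  fx <- invitro_fixture(n = 10)
  expect_error(kinn_fit(fx$arch, fx$X, c(rep(1, 9), -1)),
               "strictly positive")
})

test_that("eigen head agrees with the KA head when the cut step is rate-limiting", {
  fx <- invitro_fixture(n = 5)
  arch_ka <- fx$arch
  arch_ei <- kinn_architecture(fx$cfg$scheme, fx$arch$windows, fx$cfg$L, 4L,
                               output_head = "eigen_rate")
  p <- kinn_init(arch_ka, labels = 0.01, init_sd = 0.1, seed = 6)
  p$kernels[["k30"]]$W[] <- 0
  p$kernels[["k30"]]$b <- log(0.01) - 8   # cut far slower than everything
  yka <- kinn_forward(arch_ka, p, fx$X)$y
  yei <- kinn_forward(arch_ei, p, fx$X)$y
  expect_lt(max(abs(yka - yei) / yei), 0.05)
})

test_that("a KINN has far fewer parameters than a generic backbone model", {
  fx <- invitro_fixture(n = 2)
  kinn_n <- length(coef(kinn_fit(fx$arch, fx$X, fx$data$cleavage_rate[1:2],
                                 config = train_config(epochs = 1))))
  pk <- planted_invivo_kinn()
  tm <- transfer_model(pk, backbone_spec(conv1 = "k5", conv2 = "k3",
                                         recurrent = "wide"), seed = 1)
  backbone_n <- length(unlist(tm$params))
  expect_gt(backbone_n / kinn_n, 50)
})
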