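test_that("rate matrix has the Cas9 cycle sparsity/sign pattern and conserves occupancy", {
  sc <- cas9_scheme(Du = 2)
  set.seed(1)
  r <- random_rates(sc)
  K <- build_rate_matrix(sc, r, conservative = TRUE)
  # pattern of the four-state cycle with Du on the binding step
  expect_equal(K[1, 1], -r[["k01"]] * 2)
  expect_equal(K[2, 1], r[["k01"]] * 2)
  expect_equal(K[1, 2], r[["k10"]])
  expect_equal(K[1, 4], r[["k30"]])
  expect_equal(K[4, 1], 0)
  expect_equal(K[3, 1], 0)
  expect_equal(K[4, 4], -(r[["k30"]] + r[["k32"]]))
  # conservation holds for arbitrary random schemes too
  for (i in 1:10) {
    sch <- random_scheme(sample(3:6, 1))
    Kc <- build_rate_matrix(sch, random_rates(sch), conservative = TRUE)
    expect_lt(max(abs(colSums(Kc))), 1e-12 * max(abs(Kc)))
  }
})

test_that("non-conservative matrix removes only the product return entry", {
  sc <- cas9_scheme()
  set.seed(2)
  r <- random_rates(sc)
  K <- build_rate_matrix(sc, r, conservative = TRUE)
  Kp <- build_rate_matrix(sc, r, conservative = FALSE)
  # independent hand-built oracle: zero the (0,3) return of the cut edge
  oracle <- K
  oracle[1, 4] <- 0
  expect_equal(unclass(Kp), unclass(oracle), ignore_attr = TRUE)
})

test_that("rate validation rejects missing and nonpositive rates", {
  sc <- cas9_scheme()
  r <- cas9_rates_unit()
  expect_error(build_rate_matrix(sc, r[-1], TRUE), "missing rate")
  r2 <- r; r2["k12"] <- -1
  expect_error(build_rate_matrix(sc, r2, TRUE), "strictly positive")
})

test_that("KA enumeration matches structure on small schemes and brute force up to 5 states", {
  two <- kinetic_scheme(2, c("k01", "k10"))
  d2 <- enumerate_ka_diagrams(two)
  expect_length(d2$diagrams, 2)
  expect_setequal(d2$terminal, c(0, 1))
  # terminal 0 diagram uses the edge INTO 0 (k10), terminal 1 uses k01
  expect_equal(unname(d2$binary_matrix[d2$terminal == 0, "k10"]), 1)
  expect_equal(unname(d2$binary_matrix[d2$terminal == 1, "k01"]), 1)

  chain <- kinetic_scheme(3, c("k01", "k10", "k12", "k21"))
  d3 <- enumerate_ka_diagrams(chain)
  expect_length(d3$diagrams, 3)
  # diagram weights: kappa = k10*k21, k01*k21, k01*k12 per terminal state
  r <- c(k01 = 2, k10 = 3, k12 = 5, k21 = 7)
  s <- steady_state_ka(chain, r, d3)
  kappa <- c(3 * 7, 2 * 7, 2 * 5)
  expect_equal(unname(s), kappa / sum(kappa), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:15) {
    sch <- random_scheme(sample(3:5, 1), p_extra = 0.4)
    got <- enumerate_ka_diagrams(sch)
    want <- brute_force_diagrams(sch)
    key <- function(edges, term) paste(term, paste(edges, collapse = ","))
    expect_setequal(
      vapply(seq_along(got$diagrams),
             function(k) key(got$diagrams[[k]], got$terminal[k]), ""),
      vapply(want, function(w) key(w$edges, w$terminal), ""))
    expect_true(all(rowSums(got$binary_matrix) == sch$n_states - 1L))
  }
})

test_that("KA enumeration requires strong connectivity and names the unreachable state", {
  sc <- kinetic_scheme(3, c("k01", "k12"))  # no path back to 0
  expect_error(enumerate_ka_diagrams(sc), "unreachable")
})

test_that("KA steady state equals the null-space solution and known closed forms", {
  two <- kinetic_scheme(2, c("k01", "k10"))
  expect_equal(unname(steady_state_ka(two, c(k01 = 2, k10 = 1))),
               c(1 / 3, 2 / 3), tolerance = 1e-12)
  # symmetric reversible cycle with equal rates is uniform
  cyc <- kinetic_scheme(4, c("k01", "k10", "k12", "k21", "k23", "k32",
                             "k30", "k03"))
  req <- rep(1, 8); names(req) <- cyc$edges$symbol
  expect_equal(unname(steady_state_ka(cyc, req)), rep(0.25, 4),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:40) {
    sch <- random_scheme(sample(4:6, 1))
    r <- random_rates(sch)
    expect_lt(max(abs(steady_state_ka(sch, r) -
                      null_space_steady_state(sch, r))), 1e-9)
  }
})

test_that("propagate solves the kinetic ODE and relaxes to the KA steady state", {
  sc <- cas9_scheme()
  set.seed(3)
  r <- random_rates(sc, log10_range = c(-1, 1))
  s0 <- c(1, 0, 0, 0)
  expect_identical(propagate(sc, r, s0, 0), s0)
  expect_error(propagate(sc, r, s0, -1), "nonnegative")
  st <- propagate(sc, r, s0, 0.37)
  expect_equal(sum(st), 1, tolerance = 1e-9)
  sinf <- steady_state_ka(sc, r)
  tbig <- 1e6 / min(r)
  expect_equal(unname(propagate(sc, r, s0, tbig)), unname(sinf),
               tolerance = 1e-6)
  skip_if_not_installed("deSolve")
  K <- build_rate_matrix(sc, r, conservative = TRUE)
  sol <- deSolve::lsoda(s0, c(0, 0.37), function(t, y, p) list(K %*% y),
                        NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(st, unname(sol[2, -1]), tolerance = 1e-9)
})

test_that("activity sums flux over the declared measurable transitions", {
  sc <- cas9_scheme()
  r <- cas9_rates_unit(); r["k30"] <- 0.5
  occ <- c(0.5, 0.2, 0.1, 0.2)
  expect_equal(activity(sc, r, occ), 0.5 * 0.2)
  # linearity over two activity edges
  sc2 <- kinetic_scheme(3, c("k01", "k10", "k12", "k21", "k20", "k02"),
                        activity_edges = c("k12", "k20"))
  r2 <- c(k01 = 1, k10 = 2, k12 = 3, k21 = 1, k20 = 4, k02 = 1)
  occ2 <- c(0.3, 0.5, 0.2)
  one <- function(e) {
    s <- sc2; s$activity_edges <- e
    activity(s, r2, occ2)
  }
  expect_equal(activity(sc2, r2, occ2), one("k12") + one("k20"))
  sc$activity_edges <- character()
  expect_error(activity(sc, r, occ), "no activity edges")
})

test_that("slow eigen-rate is the slowest nonzero decay mode", {
  # single-exponential decay: irreversible 2-state
  two <- kinetic_scheme(2, "k01", activity_edges = "k01",
                        binding_edge = "k01")
  expect_equal(slow_eigen_rate(two, c(k01 = 0.3)), 0.3, tolerance = 1e-12)
  # conservative matrix always has an exactly zero eigenvalue
  sc <- cas9_scheme()
  set.seed(4)
  for (i in 1:10) {
    r <- random_rates(sc)
    K <- build_rate_matrix(sc, r, conservative = TRUE)
    ev <- eigen(K, only.values = TRUE)$values
    expect_lt(min(Mod(ev)), 1e-10 * max(Mod(ev)))
  }
})

test_that("characteristic-polynomial identities hold for the Cas9 cycle", {
  sc <- cas9_scheme()
  id <- char_poly_identities(sc, cas9_rates_unit())
  expect_equal(id$det_Kprime, 1, tolerance = 1e-12)
  expect_equal(id$cycle_product, 1, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    r <- random_rates(sc, log10_range = c(-1, 1))
    id <- char_poly_identities(sc, r)
    expect_equal(id$det_Kprime, id$cycle_product,
                 tolerance = 1e-10)
    expect_equal(id$a1_K, id$a1_Kprime, tolerance = 1e-10)
    expect_equal(id$a1_K, id$sum_kappa, tolerance = 1e-10)
    # activity at the KA steady state equals a0/a1
    s <- steady_state_ka(sc, r)
    expect_equal(activity(sc, r, s), id$a0_over_a1, tolerance = 1e-9)
  }
  expect_error(char_poly_identities(kinetic_scheme(3, c("k01", "k10")),
                                    c(k01 = 1, k10 = 1)),
               "4-state")
})
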