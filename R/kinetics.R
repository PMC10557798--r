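#' Build the rate matrix of a kinetic scheme
#'
#' For a scheme with rates \eqn{k_{\alpha\beta}} the conservative rate matrix
#' has entries \eqn{K_{\alpha\beta} = k_{\beta\alpha}} for
#' \eqn{\alpha \neq \beta} and \eqn{K_{\alpha\alpha} = -\sum_\gamma
#' k_{\alpha\gamma}}, so that \eqn{ds/dt = K s} conserves total occupancy
#' (every column sums to zero). With \code{conservative = FALSE} the
#' off-diagonal return entries of the activity (product-forming) edges are
#' removed, giving the depleting-reservoir generator \eqn{K'} whose
#' determinant is nonzero: product leaves the system instead of being
#' recycled into the unbound state. The binding edge's rate is multiplied by
#' the reservoir concentration in both variants.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param rates named rate vector (see \code{\link{validate_rates}}).
#' @param conservative logical; \code{FALSE} requires the scheme to declare
#'   both a binding edge and at least one activity edge.
#' @return an \code{n_states x n_states} matrix with attribute
#'   \code{"conservative"}.
#' @export
build_rate_matrix <- function(scheme, rates, conservative = TRUE) {
  r <- effective_rates(scheme, rates)
  n <- scheme$n_states
  K <- matrix(0, n, n)
  for (i in seq_len(nrow(scheme$edges))) {
    a <- scheme$edges$from[i]; b <- scheme$edges$to[i]; k <- r[i]
    K[b + 1L, a + 1L] <- K[b + 1L, a + 1L] + k
    K[a + 1L, a + 1L] <- K[a + 1L, a + 1L] - k
  }
  if (!conservative) {
    if (!length(scheme$activity_edges))
      stop("non-conservative matrix requires the scheme to declare its ",
           "product-forming (activity) edge(s)")
    if (is.null(scheme$binding_edge))
      stop("non-conservative matrix requires the scheme to declare its ",
           "reservoir-binding edge")
    for (s in scheme$activity_edges) {
      i <- match(s, scheme$edges$symbol)
      a <- scheme$edges$from[i]; b <- scheme$edges$to[i]
      K[b + 1L, a + 1L] <- K[b + 1L, a + 1L] - r[i]
    }
  }
  attr(K, "conservative") <- conservative
  K
}

#' Propagate a state occupancy through time
#'
#' Evaluates the solution of the linear kinetic system \eqn{ds/dt = K s}:
#' \eqn{s(t) = e^{Kt} s(0)}, which relaxes toward the steady state
#' \eqn{s_\infty} along K's nonpositive eigenvalues. Computed by matrix
#' exponential action (\code{Matrix::expm}). Total occupancy is preserved.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param rates named rate vector.
#' @param s0 initial occupancy (length \code{n_states}, nonnegative, sums to 1).
#' @param t time in seconds, \eqn{t \ge 0}.
#' @return occupancy vector at time \code{t}.
#' @export
propagate <- function(scheme, rates, s0, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a nonnegative scalar time in seconds")
  s0 <- as.numeric(s0)
  if (length(s0) != scheme$n_states || any(s0 < 0) ||
      abs(sum(s0) - 1) > 1e-9)
    stop("s0 must be a nonnegative occupancy vector summing to 1")
  if (t == 0) return(s0)
  K <- build_rate_matrix(scheme, rates, conservative = TRUE)
  as.numeric(Matrix::expm(Matrix::Matrix(K * t)) %*% s0)
}

#' Activity (measurable production rate) at a given occupancy
#'
#' The activity \eqn{\nu = \sum_{\alpha\beta \in act}
#' \tilde k_{\alpha\beta} s_\alpha} sums the flux through the scheme's
#' activity-producing transitions.
#'
#' @param scheme a \code{\link{kinetic_scheme}} with nonempty
#'   \code{activity_edges}.
#' @param rates named rate vector.
#' @param occupancy normalized occupancy vector.
#' @return nonnegative scalar flux.
#' @export
activity <- function(scheme, rates, occupancy) {
  if (!length(scheme$activity_edges))
    stop("scheme declares no activity edges")
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != scheme$n_states || abs(sum(occupancy) - 1) > 1e-6)
    stop("occupancy must be normalized (length n_states, sum 1)")
  r <- effective_rates(scheme, rates)
  idx <- match(scheme$activity_edges, scheme$edges$symbol)
  sum(r[idx] * occupancy[scheme$edges$from[idx] + 1L])
}

#' Slowest relaxation rate of the depleting-reservoir system
#'
#' Returns \eqn{-\lambda} for the nonzero eigenvalue \eqn{\lambda} of the
#' non-conservative generator \eqn{K'} closest to zero (numerically zero
#' modes, which arise only in degenerate topologies such as a bare
#' product-accumulating state, are excluded). All eigenvalues of
#' \eqn{K'} have nonpositive real parts; the one of smallest magnitude is
#' the slowest decay mode and governs the observed single-exponential
#' cleavage, so this quantity is the simulated (and learned) cleavage rate.
#' Equal-magnitude candidates are tie-broken by larger real part; a slow
#' mode with a non-negligible imaginary component triggers a warning
#' reporting both components.
#'
#' @param scheme a \code{\link{kinetic_scheme}} declaring binding and
#'   activity edges.
#' @param rates named rate vector.
#' @param imag_tol relative imaginary-part tolerance before warning.
#' @return positive scalar decay rate (s^-1).
#' @export
slow_eigen_rate <- function(scheme, rates, imag_tol = 1e-8) {
  Kp <- build_rate_matrix(scheme, rates, conservative = FALSE)
  ev <- eigen(Kp, only.values = TRUE)$values
  mod <- Mod(ev)
  nz <- mod > 1e-12 * max(mod)   # the slow mode is the smallest NONZERO one
  if (!any(nz)) stop("all eigenvalues are numerically zero")
  ev <- ev[nz]; mod <- mod[nz]
  cand <- which(mod <= min(mod) * (1 + 1e-12))
  if (length(cand) > 1L) cand <- cand[which.max(Re(ev[cand]))]
  lam <- ev[cand]
  scale <- max(mod)
  if (abs(Im(lam)) > imag_tol * max(scale, 1))
    warning(sprintf(
      "slow mode is complex: Re = %.6g, Im = %.6g; returning -Re", Re(lam), Im(lam)))
  -Re(lam)
}

# Determinant with a cancellation-aware path for tridiagonal matrices
# (sequential elimination without pivoting telescopes the cycle products
# almost exactly, where a generic LU loses many digits); falls back to
# base det() otherwise.
det_struct <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[1L, 1L])
  if (any(M[abs(row(M) - col(M)) > 1L] != 0)) return(det(M))
  A <- M
  d <- 1
  for (i in seq_len(n)) {
    p <- A[i, i]
    if (p == 0) return(det(M))
    d <- d * p
    if (i < n) {
      f <- A[i + 1L, i] / p
      A[i + 1L, i] <- 0
      A[i + 1L, i + 1L] <- A[i + 1L, i + 1L] - f * A[i, i + 1L]
    }
  }
  d
}

# coefficient a_k of x^k in the monic characteristic polynomial
# det(xI - K) = sum_m x^(N-m) (-1)^m e_m(K), e_m = sum of m x m principal minors
char_poly_coef <- function(K, k) {
  n <- nrow(K)
  m <- n - k
  if (m == 0L) return(1)
  combs <- utils::combn(n, m)
  s <- sum(apply(combs, 2L, function(ix) det_struct(K[ix, ix, drop = FALSE])))
  (-1)^m * s
}

#' Characteristic-polynomial identities of the Cas9 cleavage cycle
#'
#' For the four-state cycle (with cut edge \eqn{k_{30} = k_{cut}}), the
#' conservative matrix \eqn{K} and its depleting-reservoir counterpart
#' \eqn{K'} satisfy two exact identities: \eqn{\det K' = k_{01} k_{12}
#' k_{23} k_{cut}} (with the binding rate scaled by the reservoir
#' concentration), and the linear characteristic-polynomial coefficients
#' agree with the total King-Altman diagram weight,
#' \eqn{a_1(K) = a_1(K') = \sum_\ell \kappa_\ell}. The ratio of the two is
#' the steady-state activity, and \eqn{-\lambda \approx a_0/a_1} for the
#' slow mode. This function returns both sides of each identity so they can
#' be asserted against one another.
#'
#' @param scheme the four-state cycle scheme (see \code{\link{cas9_scheme}}).
#' @param rates named rate vector.
#' @return a list with \code{det_Kprime}, \code{cycle_product},
#'   \code{a1_K}, \code{a1_Kprime}, \code{sum_kappa}, and \code{a0_over_a1}.
#' @export
char_poly_identities <- function(scheme, rates) {
  ref <- cas9_scheme()
  same <- scheme$n_states == 4L &&
    setequal(scheme$edges$symbol, ref$edges$symbol)
  if (!same)
    stop("char_poly_identities requires the 4-state Cas9 cycle topology ",
         "(edges k01 k10 k12 k21 k23 k32 k30)")
  r <- effective_rates(scheme, rates)
  K  <- build_rate_matrix(scheme, rates, conservative = TRUE)
  Kp <- build_rate_matrix(scheme, rates, conservative = FALSE)
  dg <- enumerate_ka_diagrams(scheme)
  logk <- log(r)[dg$edge_symbols]
  sum_kappa <- sum(exp(as.numeric(dg$binary_matrix %*% logk)))
  dKp <- char_poly_coef(Kp, 0L)  # a0 = (-1)^N det K' = det K' for N = 4
  list(det_Kprime   = dKp,
       cycle_product = unname(r["k01"] * r["k12"] * r["k23"] * r["k30"]),
       a1_K      = char_poly_coef(K, 1L),
       a1_Kprime = char_poly_coef(Kp, 1L),
       sum_kappa = sum_kappa,
       a0_over_a1 = dKp / char_poly_coef(Kp, 1L))
}
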