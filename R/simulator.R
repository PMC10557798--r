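#' Configure the Arrhenius in vitro simulator
#'
#' The simulator plants a known sequence-to-rate dependence for the
#' four-state Cas9 cleavage cycle: each of the seven rate constants is
#' controlled by its own disjoint window of nucleotide pairings, and rates
#' follow the Arrhenius form
#' \eqn{k_{\alpha\beta} = k_0 \exp[\mp (k_B T)^{-1} \sum_{i \in \Omega}
#' \Delta\bar G(x_i, \xi_i)]}, the sign being negative for forward
#' transitions (\eqn{\alpha < \beta}) and positive for backward ones.
#' Free-energy increments per pairing class are fixed at \eqn{-1} for
#' complementary pairs; the three mismatch classes draw once per transition
#' from \eqn{\{-0.1, 0.1, 1\}} under the seed and are frozen in the
#' returned config, so a dataset is fully reproducible from (config, seed).
#' \eqn{\Delta\bar G} values are dimensionless multiples of \eqn{k_B T}
#' (so \code{kBT = 1}).
#'
#' @param L sequence length (default 50).
#' @param active_region 0-based half-open window of label-determining
#'   positions (default \code{c(5, 40)}).
#' @param window_length length of each per-rate window (default 5; the
#'   windows tile the active region, one per rate, in edge order
#'   k01, k10, k12, k21, k23, k32, k30).
#' @param k0 baseline rate, s^-1 (s^-1 nMol^-1 for the binding step).
#' @param kBT thermal energy scale (default 1).
#' @param Du unbound-DNA reservoir concentration, nMol.
#' @param mismatch_values candidate free-energy increments for mismatch
#'   classes.
#' @param seed integer seed freezing the mismatch table.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(L = 50L, active_region = c(5L, 40L), window_length = 5L,
                       k0 = 0.01, kBT = 1, Du = 1,
                       mismatch_values = c(-0.1, 0.1, 1), seed = 1L) {
  scheme <- cas9_scheme(Du)
  n_edges <- nrow(scheme$edges)
  active_len <- active_region[2] - active_region[1]
  if (n_edges * window_length != active_len)
    stop("active region length (", active_len, ") must equal n_rates (",
         n_edges, ") x window_length (", window_length, ")")
  windows <- data.frame(symbol = scheme$edges$symbol,
                        start = active_region[1] + (seq_len(n_edges) - 1L) * window_length,
                        end   = active_region[1] + seq_len(n_edges) * window_length)
  set.seed(seed)
  dG <- matrix(NA_real_, n_edges, 4L,
               dimnames = list(scheme$edges$symbol,
                               c("match", "mm1", "mm2", "mm3")))
  dG[, "match"] <- -1
  dG[, 2:4] <- sample(mismatch_values, 3L * n_edges, replace = TRUE)
  structure(list(L = as.integer(L), active_region = as.integer(active_region),
                 window_length = as.integer(window_length),
                 windows = windows, dG_table = dG, k0 = k0, kBT = kBT,
                 Du = Du, scheme = scheme, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Arrhenius simulator config: L =", x$L, ", active region [",
      x$active_region[1], ",", x$active_region[2], "), ",
      nrow(x$windows), "windows of", x$window_length, "nt\n")
  cat("  k0 =", x$k0, "s^-1, kBT =", x$kBT, ", Du =", x$Du, "nMol, seed =",
      x$seed, "\n")
  invisible(x)
}

#' Ground-truth Arrhenius rates for one sequence pairing
#'
#' @param config a \code{\link{sim_config}}.
#' @param guide,target length-L sequences.
#' @return named rate vector over the scheme's edges.
#' @export
arrhenius_rates <- function(config, guide, target) {
  g <- canon_base(seq_chars(guide)); t <- canon_base(seq_chars(target))
  if (length(g) != config$L || length(t) != config$L)
    stop("sequences must have length L = ", config$L)
  cls <- pairing_class(g, t)
  arrhenius_from_class(config, matrix(cls, nrow = 1L))[1L, ]
}

# vectorized core: cls is an n x L matrix of pairing classes (1..4)
arrhenius_from_class <- function(config, cls) {
  sch <- config$scheme
  n <- nrow(cls)
  E <- nrow(config$windows)
  rates <- matrix(NA_real_, n, E, dimnames = list(NULL, config$windows$symbol))
  forward <- sch$edges$from < sch$edges$to
  for (e in seq_len(E)) {
    w <- config$windows[e, ]
    idx <- (w$start + 1L):w$end           # 0-based half-open -> 1-based
    dg <- matrix(config$dG_table[e, ][cls[, idx, drop = FALSE]],
                 nrow = n)
    ssum <- rowSums(dg)
    sgn <- if (forward[e]) -1 else 1
    rates[, e] <- config$k0 * exp(sgn * ssum / config$kBT)
  }
  rates
}

# fast slow-mode rate for the 4-state cycle given a named rate row
cas9_slow_rate <- function(k, Du = 1) {
  k01 <- k[["k01"]] * Du
  Kp <- matrix(c(-k01,        k[["k10"]],               0,                        0,
                 k01,        -(k[["k10"]] + k[["k12"]]), k[["k21"]],              0,
                 0,           k[["k12"]],               -(k[["k21"]] + k[["k23"]]), k[["k32"]],
                 0,           0,                         k[["k23"]],              -(k[["k30"]] + k[["k32"]])),
               4L, 4L, byrow = TRUE)
  ev <- eigen(Kp, only.values = TRUE)$values
  -Re(ev[which.min(Mod(ev))])
}

#' Simulate the in vitro cleavage-rate benchmark
#'
#' Draws \code{n} i.i.d. uniform-random guide/target pairings of length L,
#' computes every transition rate from the Arrhenius dependence planted in
#' \code{config}, and labels each record with the cleavage rate: minus the
#' eigenvalue closest to zero of the depleting-reservoir rate matrix built
#' from those rates. Only the active-region positions influence the label.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n number of sequence pairs.
#' @param seed integer seed (independent of the config's table-freezing
#'   seed).
#' @return a data.frame with columns \code{guide_seq}, \code{target_seq},
#'   one column per rate constant, and \code{cleavage_rate}.
#' @export
simulate_invitro <- function(config, n, seed = 1L) {
  set.seed(seed)
  L <- config$L
  gmat <- matrix(sample(DNA_BASES, n * L, replace = TRUE), n, L)
  tmat <- matrix(sample(DNA_BASES, n * L, replace = TRUE), n, L)
  comp <- WC_COMP[gmat]
  cls <- matrix(1L + (match(tmat, DNA_BASES) - match(comp, DNA_BASES)) %% 4L,
                n, L)
  rates <- arrhenius_from_class(config, cls)
  lab <- vapply(seq_len(n), function(i) cas9_slow_rate(rates[i, ], config$Du), 0)
  out <- data.frame(guide_seq = apply(gmat, 1L, paste, collapse = ""),
                    target_seq = apply(tmat, 1L, paste, collapse = ""),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rates))
  out$cleavage_rate <- lab
  out
}

# n x L x 4 pairing-encoding array for a simulated dataset
pairing_array <- function(dataset, L) {
  n <- nrow(dataset)
  X <- array(0, c(n, L, 4L))
  for (i in seq_len(n))
    X[i, , ] <- encode_pairing(dataset$guide_seq[i], dataset$target_seq[i], L)
  X
}

#' Construct a planted KINN on the 25 x 13 alignment encoding
#'
#' Ground-truth generator for the synthetic in vivo benchmark: a four-state
#' cycle KINN whose seven rate windows tile the guide-facing positions of
#' the 25-column encoding (kernel size 1), with random kernel weights of
#' moderate scale so that substitutions, insertions and deletions move the
#' rates over a realistic range.
#'
#' @param seed integer seed.
#' @param init_sd kernel weight scale.
#' @param Du reservoir concentration.
#' @return list with \code{architecture} and \code{parameters} (the shape
#'   \code{\link{transfer_model}} expects of a pretrained KINN).
#' @export
planted_invivo_kinn <- function(seed = 1L, init_sd = 0.6, Du = 1) {
  scheme <- cas9_scheme(Du)
  windows <- data.frame(symbol = scheme$edges$symbol,
                        start = 3L + 3L * (0:6), end = 6L + 3L * (0:6),
                        kernel = 1L)
  arch <- kinn_architecture(scheme, windows, input_length = 25L,
                            channels = 13L)
  params <- kinn_init(arch, labels = 0.01, init_sd = init_sd, seed = seed)
  list(architecture = arch, parameters = params)
}

#' Simulate a binary in vivo editing benchmark
#'
#' Synthetic stand-in for a compiled in vivo off-target dataset: random
#' guide/PAM/target alignments (substitutions, and optionally 1-nt
#' insertions or deletions) are scored by a planted KINN operating on the
#' 13-channel encoding; a context effect \eqn{\delta} -- an additive per-G
#' bonus computed from the aligned target sequence, plus Gaussian noise --
#' perturbs the log cleavage rate, and binary labels are drawn from
#' \eqn{p = \mathrm{sigmoid}(a(\log k + \delta - \theta))} with the
#' threshold \eqn{\theta} placed at the quantile giving the requested
#' positive fraction. The true \eqn{\delta} is stored for recovery tests.
#'
#' @param planted_kinn a \code{kinn_model} (or list with
#'   \code{architecture}, \code{parameters}) on 25 x 13 input.
#' @param n number of records.
#' @param n_guides number of distinct guides (labels are split by guide
#'   downstream).
#' @param context_effect list with \code{per_G} (additive log-rate bonus
#'   per G in the aligned target, centered) and \code{noise_sd}.
#' @param positive_fraction target fraction of positive labels.
#' @param slope logistic slope \eqn{a}.
#' @param sub_prob per-position substitution probability.
#' @param indel_prob probability a record carries one 1-nt insertion (half)
#'   or deletion (half).
#' @param seed integer seed.
#' @return list of class \code{"invivo_sim"}: \code{table} (data.frame with
#'   guide, pam, target_alignment, guide_id, log_rate, true_delta, label)
#'   and \code{X} (n x 25 x 13 encoding array).
#' @export
simulate_invivo <- function(planted_kinn, n = 5000L, n_guides = 40L,
                            context_effect = list(per_G = 0.6, noise_sd = 0.1),
                            positive_fraction = 0.05, slope = 3,
                            sub_prob = 0.08, indel_prob = 0.04, seed = 1L) {
  set.seed(seed)
  guides <- replicate(n_guides,
                      paste(sample(DNA_BASES, 20L, replace = TRUE), collapse = ""))
  gid <- sample.int(n_guides, n, replace = TRUE)
  pam <- replicate(n, paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = ""))
  tab <- data.frame(guide = guides[gid], pam = pam,
                    guide_id = gid, stringsAsFactors = FALSE)
  tab$target_alignment <- vapply(seq_len(n), function(i) {
    ref <- seq_chars(paste0(tab$pam[i], tab$guide[i]))
    al <- ref
    subs <- which(stats::runif(23L) < sub_prob)
    for (p in subs) al[p] <- sample(setdiff(DNA_BASES, ref[p]), 1L)
    if (stats::runif(1) < indel_prob) {
      pos <- sample(4:23, 1L)
      if (stats::runif(1) < 0.5) {
        al <- append(al, tolower(sample(DNA_BASES, 1L)), after = pos)
      } else {
        al[pos] <- "-"
      }
    }
    paste(al, collapse = "")
  }, "")
  X <- array(0, c(n, 25L, 13L))
  for (i in seq_len(n))
    X[i, , ] <- encode_invivo(tab$guide[i], tab$pam[i], tab$target_alignment[i])
  rate <- kinn_forward(planted_kinn$architecture, planted_kinn$parameters, X)$y
  # context covariate: G content of the aligned target (reference G kept,
  # substituted-to-G, or inserted G), centered
  sub_any <- X[, , 5L] + X[, , 6L] + X[, , 7L] + X[, , 8L]
  gcount <- rowSums(X[, , 3L] * (1 - sub_any - X[, , 13L])) +
    rowSums(X[, , 7L]) + rowSums(X[, , 11L])
  delta <- context_effect$per_G * (gcount - mean(gcount)) +
    stats::rnorm(n, 0, context_effect$noise_sd)
  eta <- log(pmax(rate, 1e-12)) + delta
  theta <- stats::quantile(eta, 1 - positive_fraction, names = FALSE)
  p <- stats::plogis(slope * (eta - theta))
  lab <- stats::rbinom(n, 1L, p)
  if (all(lab == lab[1L])) {
    warning("degenerate single-class label draw; resampling once")
    lab <- stats::rbinom(n, 1L, p)
  }
  tab$log_rate <- log(pmax(rate, 1e-12))
  tab$true_delta <- delta
  tab$label <- lab
  structure(list(table = tab, X = X), class = "invivo_sim")
}
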