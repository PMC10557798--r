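#' Specify a KINN architecture
#'
#' A KINN maps an encoded sequence to one log rate constant per scheme edge
#' through a single-filter convolution over a per-rate window
#' (\eqn{\log k_{\alpha\beta} = \sum \mathrm{Conv}(x_{i:j}; W_{\alpha\beta})
#' + b_{\alpha\beta}}), pushes the rates through the static King-Altman
#' diagram layer to get steady-state occupancies, and reads out the
#' measurable activity through a small trainable link head
#' \eqn{y = \sigma_o(\sigma_\nu(\nu W_t + b_t) W_o + b_o)}. With
#' \code{output_head = "eigen_rate"} the King-Altman activity is replaced
#' by the slowest relaxation rate of the depleting-reservoir matrix built
#' from the predicted rates.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param windows data.frame with columns \code{symbol}, \code{start},
#'   \code{end} (0-based half-open window on the encoded input), and
#'   \code{kernel} (convolution kernel size \code{d}, \code{1 <= d <= end -
#'   start}); exactly one row per scheme edge.
#' @param input_length number of encoded positions (e.g. 50 for the pairing
#'   encoding, 25 for the 13-channel alignment encoding).
#' @param channels number of encoding channels (4 or 13).
#' @param output_head \code{"ka_steady_state"} or \code{"eigen_rate"}.
#' @param link link-head specification from \code{\link{kinn_link}}.
#' @return an object of class \code{"kinn_architecture"}.
#' @export
kinn_architecture <- function(scheme, windows, input_length, channels = 4L,
                              output_head = c("ka_steady_state", "eigen_rate"),
                              link = kinn_link()) {
  output_head <- match.arg(output_head)
  windows <- as.data.frame(windows)
  if (!all(c("symbol", "start", "end", "kernel") %in% names(windows)))
    stop("windows needs columns symbol, start, end, kernel")
  sym <- scheme$edges$symbol
  if (!setequal(windows$symbol, sym) || nrow(windows) != length(sym))
    stop("windows must contain exactly one row per scheme edge")
  windows <- windows[match(sym, windows$symbol), ]
  rownames(windows) <- NULL
  bad <- windows$start < 0 | windows$end > input_length |
    windows$start >= windows$end |
    windows$kernel < 1 | windows$kernel > windows$end - windows$start
  if (any(bad))
    stop("invalid window spec for: ", paste(windows$symbol[bad], collapse = ", "))
  if (output_head == "eigen_rate" &&
      (is.null(scheme$binding_edge) || !length(scheme$activity_edges)))
    stop("eigen_rate head requires binding and activity edges on the scheme")
  structure(list(scheme = scheme, windows = windows,
                 input_length = as.integer(input_length),
                 channels = as.integer(channels),
                 output_head = output_head, link = link,
                 diagrams = enumerate_ka_diagrams(scheme)),
            class = "kinn_architecture")
}

#' @rdname kinn_architecture
#' @param hidden width of the link-head hidden layer \eqn{W_t}.
#' @param act_nu,act_o activations \eqn{\sigma_\nu, \sigma_o}: one of
#'   \code{"identity"}, \code{"softplus"}, \code{"exponential"}.
#' @param trainable logical; by default the link head stays at the
#'   initialized identity (\eqn{y = \nu}, the raw activity), matching the
#'   default assumption that the activity-measurement relation is linear. A
#'   trainable nonlinear head is opt-in for assays where that relation is
#'   known to be nonlinear.
#' @export
kinn_link <- function(hidden = 1L, act_nu = "identity", act_o = "identity",
                      trainable = FALSE) {
  ok <- c("identity", "softplus", "exponential")
  stopifnot(act_nu %in% ok, act_o %in% ok, hidden >= 1L)
  list(hidden = as.integer(hidden), act_nu = act_nu, act_o = act_o,
       trainable = isTRUE(trainable))
}

#' @export
print.kinn_architecture <- function(x, ...) {
  cat("KINN architecture:", x$scheme$n_states, "states,",
      nrow(x$windows), "rate windows on", x$input_length, "x", x$channels,
      "input;", x$output_head, "head\n")
  print(x$windows, row.names = FALSE)
  invisible(x)
}

act_fun <- function(name) switch(name,
  identity    = list(f = function(x) x,            df = function(x) rep(1, length(x))),
  softplus    = list(f = function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
                     df = function(x) stats::plogis(x)),
  exponential = list(f = exp, df = exp))

#' Initialize KINN parameters
#'
#' Kernel weights draw from a small-variance symmetric normal; per-rate
#' biases start at the log of the label median so that initial rates sit in
#' the label range and the King-Altman softmax is unsaturated; the link
#' head starts at the identity (\eqn{W_t = W_o = 1}, zero biases).
#'
#' @param arch a \code{\link{kinn_architecture}}.
#' @param labels training labels (used only for the bias scale); defaults
#'   to 1.
#' @param init_sd kernel weight s.d.
#' @param seed integer seed.
#' @return an object of class \code{"kinn_parameters"}: list with
#'   \code{kernels} (per-edge list of \code{W} (d x channels) and \code{b})
#'   and \code{link} (\code{Wt}, \code{bt}, \code{Wo}, \code{bo}).
#' @export
kinn_init <- function(arch, labels = 1, init_sd = 0.05, seed = 1L) {
  set.seed(seed)
  b0 <- log(stats::median(labels))
  kernels <- lapply(seq_len(nrow(arch$windows)), function(e) {
    d <- arch$windows$kernel[e]
    list(W = matrix(stats::rnorm(d * arch$channels, 0, init_sd),
                    d, arch$channels),
         b = b0)
  })
  names(kernels) <- arch$windows$symbol
  h <- arch$link$hidden
  structure(list(kernels = kernels,
                 link = list(Wt = matrix(1, 1L, h), bt = rep(0, h),
                             Wo = matrix(1, h, 1L), bo = 0)),
            class = "kinn_parameters")
}

# ---- parameter packing -----------------------------------------------------

params_pack <- function(params) {
  unlist(c(lapply(params$kernels, function(k) c(as.numeric(k$W), k$b)),
           list(as.numeric(params$link$Wt), params$link$bt,
                as.numeric(params$link$Wo), params$link$bo)),
         use.names = FALSE)
}

params_unpack <- function(flat, params) {
  pos <- 0L
  take <- function(k) { v <- flat[(pos + 1L):(pos + k)]; pos <<- pos + k; v }
  for (e in seq_along(params$kernels)) {
    W <- params$kernels[[e]]$W
    params$kernels[[e]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
    params$kernels[[e]]$b <- take(1L)
  }
  h <- length(params$link$bt)
  params$link$Wt <- matrix(take(h), 1L, h)
  params$link$bt <- take(h)
  params$link$Wo <- matrix(take(h), h, 1L)
  params$link$bo <- take(1L)
  params
}

# ---- feature precomputation ------------------------------------------------

# X: n x L x C array (or a single L x C matrix). For window [i, j) with
# kernel d, the log rate is linear in W: sum over the (j - i - d + 1) kernel
# placements of <W, X slice>, so per edge we precompute
# F[n, (u, c)] = sum_p X[n, i + p + u, c] and get log k = F %*% vec(W) + b.
kinn_features <- function(arch, X) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  n <- dim(X)[1L]
  lapply(seq_len(nrow(arch$windows)), function(e) {
    i <- arch$windows$start[e]; j <- arch$windows$end[e]
    d <- arch$windows$kernel[e]
    Fm <- matrix(0, n, d * arch$channels)
    for (u in seq_len(d)) {
      sl <- X[, (i + u):(j - d + u), , drop = FALSE]
      # column (c-1)*d + u, matching the column-major vec of the d x C kernel
      Fm[, (seq_len(arch$channels) - 1L) * d + u] <-
        apply(sl, c(1L, 3L), sum)
    }
    Fm
  })
}

# ---- forward / backward ----------------------------------------------------

# Full forward pass. Returns all intermediates needed by kinn_backward.
# X may be an n x L x C array, a single L x C matrix, or a precomputed
# feature list from kinn_features().
kinn_forward <- function(arch, params, X) {
  feats <- if (is.list(X) && !is.array(X)) X else kinn_features(arch, X)
  n <- nrow(feats[[1L]])
  E <- length(feats)
  logk <- matrix(0, n, E, dimnames = list(NULL, arch$windows$symbol))
  for (e in seq_len(E))
    logk[, e] <- feats[[e]] %*% as.numeric(params$kernels[[e]]$W) +
      params$kernels[[e]]$b
  sch <- arch$scheme
  offs <- rep(0, E)
  if (!is.null(sch$binding_edge) && sch$reservoir_concentration > 0)
    offs[match(sch$binding_edge, sch$edges$symbol)] <-
      log(sch$reservoir_concentration)
  logk_eff <- sweep(logk, 2L, -offs)   # logk + offs

  if (arch$output_head == "ka_steady_state") {
    dg <- arch$diagrams
    Lw <- logk_eff %*% t(dg$binary_matrix)            # n x D diagram log-weights
    m <- apply(Lw, 1L, max)
    P <- exp(Lw - m)
    Dsum <- rowSums(P)
    pnorm <- P / Dsum
    Tm <- outer(dg$terminal, seq_len(sch$n_states) - 1L, "==") * 1
    s <- pnorm %*% Tm                                  # n x S occupancies
    aidx <- match(sch$activity_edges, sch$edges$symbol)
    asrc <- sch$edges$from[aidx] + 1L
    kact <- exp(logk_eff[, aidx, drop = FALSE])
    nu <- rowSums(kact * s[, asrc, drop = FALSE])
    eig <- NULL
  } else {
    nu <- numeric(n); eig <- vector("list", n)
    for (i in seq_len(n)) {
      r <- exp(logk[i, ]); names(r) <- arch$windows$symbol
      eg <- eigen_slow(sch, r)   # build_rate_matrix applies the Du factor
      nu[i] <- eg$rate; eig[[i]] <- eg
    }
    pnorm <- s <- NULL
  }

  h <- arch$link$hidden
  a1 <- act_fun(arch$link$act_nu); a2 <- act_fun(arch$link$act_o)
  u <- matrix(nu, ncol = 1L) %*% params$link$Wt +
    matrix(params$link$bt, n, h, byrow = TRUE)
  tt <- matrix(a1$f(u), n, h)
  z <- as.numeric(tt %*% params$link$Wo) + params$link$bo
  y <- a2$f(z)
  list(y = y, z = z, tt = tt, u = u, nu = nu, s = s, pnorm = pnorm,
       logk = logk, logk_eff = logk_eff, feats = feats, eig = eig)
}

# slow mode of K' with left/right eigenvectors for the backward pass
eigen_slow <- function(scheme, rates) {
  Kp <- build_rate_matrix(scheme, rates, conservative = FALSE)
  er <- eigen(Kp); el <- eigen(t(Kp))
  i <- which.min(Mod(er$values))
  j <- which.min(Mod(el$values - er$values[i]))
  v <- er$vectors[, i]; w <- el$vectors[, j]
  list(rate = -Re(er$values[i]), v = v, w = w, denom = sum(w * v))
}

# Backward pass: dy is dLoss/dy (length n). Returns the flat gradient in
# params_pack() order.
kinn_backward <- function(arch, params, fw, dy) {
  n <- length(dy)
  h <- arch$link$hidden
  a1 <- act_fun(arch$link$act_nu); a2 <- act_fun(arch$link$act_o)
  dz <- dy * a2$df(fw$z)
  dbo <- sum(dz)
  dWo <- crossprod(fw$tt, dz)                       # h x 1
  dtt <- matrix(dz, ncol = 1L) %*%
    matrix(as.numeric(params$link$Wo), nrow = 1L)   # n x h
  du <- dtt * matrix(a1$df(fw$u), n, h)
  dbt <- colSums(du)
  dWt <- crossprod(matrix(fw$nu, ncol = 1L), du)    # 1 x h
  dnu <- as.numeric(du %*% t(params$link$Wt))       # n

  sch <- arch$scheme
  E <- ncol(fw$logk)
  dlogk <- matrix(0, n, E)
  if (arch$output_head == "ka_steady_state") {
    dg <- arch$diagrams
    aidx <- match(sch$activity_edges, sch$edges$symbol)
    asrc <- sch$edges$from[aidx] + 1L
    kact <- exp(fw$logk_eff[, aidx, drop = FALSE])
    ds <- matrix(0, n, sch$n_states)
    for (ii in seq_along(aidx)) {
      e <- aidx[ii]; sA <- asrc[ii]
      dlogk[, e] <- dlogk[, e] + dnu * kact[, ii] * fw$s[, sA]
      ds[, sA] <- ds[, sA] + dnu * kact[, ii]
    }
    G <- ds[, dg$terminal + 1L, drop = FALSE]       # n x D
    dot <- rowSums(ds * fw$s)
    dLw <- fw$pnorm * (G - dot)
    dlogk <- dlogk + dLw %*% dg$binary_matrix
  } else {
    for (i in seq_len(n)) {
      eg <- fw$eig[[i]]
      k <- exp(fw$logk_eff[i, ])
      g <- numeric(E)
      act <- sch$edges$symbol %in% sch$activity_edges
      for (e in seq_len(E)) {
        a <- sch$edges$from[e] + 1L; b <- sch$edges$to[e] + 1L
        dl <- -eg$w[a] * eg$v[a]
        if (!act[e]) dl <- dl + eg$w[b] * eg$v[a]
        g[e] <- Re(dl / eg$denom) * k[e]
      }
      dlogk[i, ] <- -dnu[i] * g                     # rate = -lambda
    }
  }
  grads <- vector("list", E)
  for (e in seq_len(E))
    grads[[e]] <- c(as.numeric(crossprod(fw$feats[[e]], dlogk[, e])),
                    sum(dlogk[, e]))
  c(unlist(grads), as.numeric(dWt), dbt, as.numeric(dWo), dbo)
}

#' Per-edge log rates predicted by a KINN
#'
#' @param arch a \code{\link{kinn_architecture}}.
#' @param params \code{\link{kinn_init}}-shaped parameters.
#' @param x encoded input: an \code{L x channels} matrix or an
#'   \code{n x L x channels} array.
#' @return named vector of log rates (matrix for array input), in scheme
#'   edge order; the reservoir factor is \emph{not} included (these are the
#'   learned rate constants).
#' @export
log_rates <- function(arch, params, x) {
  fw <- kinn_forward(arch, params, x)
  if (nrow(fw$logk) == 1L) fw$logk[1L, ] else fw$logk
}

#' King-Altman layer: occupancies from log rates
#'
#' Computes steady-state occupancies from a vector of log rates through the
#' static binary diagram matrix \eqn{B}: per-terminal-state grouped
#' log-sum-exp of the diagram weights \eqn{B \cdot \log k}, normalized
#' over all diagrams. This equals the King-Altman steady state exactly, and
#' reduces to a plain softmax over \eqn{B \log k} when each state owns a
#' single diagram.
#'
#' @param diagrams a \code{\link{enumerate_ka_diagrams}} result.
#' @param log_k numeric vector ordered as the diagram set's edge columns.
#' @return occupancy vector summing to 1.
#' @export
ka_layer <- function(diagrams, log_k) {
  stopifnot(length(log_k) == ncol(diagrams$binary_matrix))
  Lw <- as.numeric(diagrams$binary_matrix %*% log_k)
  w <- exp(Lw - max(Lw))
  s <- vapply(seq_len(diagrams$n_states) - 1L,
              function(a) sum(w[diagrams$terminal == a]), 0) / sum(w)
  names(s) <- paste0("s", seq_len(diagrams$n_states) - 1L)
  s
}

#' Extract the learned rate constants for an input
#'
#' The mechanistic hand-off: exponentiated log rates form a rate assignment
#' directly usable by the kinetic machinery (\code{\link{propagate}},
#' \code{\link{slow_eigen_rate}}, ...).
#'
#' @param object a fitted \code{kinn_model} (or a list with
#'   \code{architecture} and \code{parameters}).
#' @param x encoded input (matrix for one record, array for many).
#' @return named rate vector, or an n x edges matrix.
#' @export
extract_rates <- function(object, x) {
  lk <- log_rates(object$architecture, object$parameters, x)
  exp(lk)
}
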