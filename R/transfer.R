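# ---- backbone layer primitives (hand-rolled forward/backward) --------------

slice2 <- function(X, l) matrix(X[, l, ], dim(X)[1L], dim(X)[3L])

conv_fwd <- function(X, W, b, k, dil, act) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]; Fh <- ncol(W)
  Xc <- array(0, c(n, L, k * C))
  half <- (k - 1L) / 2
  for (u in seq_len(k)) {
    o <- (u - 1L - half) * dil
    l1 <- max(1L, 1L - o); l2 <- min(L, L - o)
    if (l1 <= l2)
      Xc[, l1:l2, (u - 1L) * C + seq_len(C)] <- X[, (l1 + o):(l2 + o), ]
  }
  Xm <- matrix(Xc, n * L, k * C)
  pre <- Xm %*% W + matrix(b, n * L, Fh, byrow = TRUE)
  out <- if (act == "relu") pmax(pre, 0) else pre
  list(out = array(out, c(n, L, Fh)), Xm = Xm, pre = pre,
       k = k, dil = dil, act = act, in_dim = c(n, L, C))
}

conv_bwd <- function(cache, W, dOut) {
  n <- cache$in_dim[1L]; L <- cache$in_dim[2L]; C <- cache$in_dim[3L]
  Fh <- ncol(W); k <- cache$k; dil <- cache$dil
  dpre <- matrix(dOut, n * L, Fh)
  if (cache$act == "relu") dpre <- dpre * (cache$pre > 0)
  dW <- crossprod(cache$Xm, dpre)
  db <- colSums(dpre)
  dXc <- array(dpre %*% t(W), c(n, L, k * C))
  dX <- array(0, c(n, L, C))
  half <- (k - 1L) / 2
  for (u in seq_len(k)) {
    o <- (u - 1L - half) * dil
    l1 <- max(1L, 1L - o); l2 <- min(L, L - o)
    if (l1 <= l2)
      dX[, (l1 + o):(l2 + o), ] <- dX[, (l1 + o):(l2 + o), ] +
        dXc[, l1:l2, (u - 1L) * C + seq_len(C)]
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

rnn_dir_fwd <- function(X, Wx, Wh, bh, rev) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; U <- ncol(Wx)
  H <- array(0, c(n, L, U))
  hprev <- matrix(0, n, U)
  idx <- if (rev) rev(seq_len(L)) else seq_len(L)
  for (l in idx) {
    h <- tanh(slice2(X, l) %*% Wx + hprev %*% Wh +
                matrix(bh, n, U, byrow = TRUE))
    H[, l, ] <- h
    hprev <- h
  }
  H
}

rnn_dir_bwd <- function(X, H, Wx, Wh, dH, rev) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; U <- ncol(Wx)
  dWx <- matrix(0, nrow(Wx), U); dWh <- matrix(0, U, U); dbh <- numeric(U)
  dX <- array(0, dim(X))
  dcarry <- matrix(0, n, U)
  idx <- if (rev) seq_len(L) else rev(seq_len(L))   # reverse of forward order
  for (l in idx) {
    h <- slice2(H, l)
    lprev <- if (rev) l + 1L else l - 1L
    hprev <- if (lprev >= 1L && lprev <= L) slice2(H, lprev)
             else matrix(0, n, U)
    dpre <- (slice2(dH, l) + dcarry) * (1 - h^2)
    dWx <- dWx + crossprod(slice2(X, l), dpre)
    dWh <- dWh + crossprod(hprev, dpre)
    dbh <- dbh + colSums(dpre)
    dX[, l, ] <- dX[, l, ] + dpre %*% t(Wx)
    dcarry <- dpre %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, dbh = dbh)
}

softmax_rows <- function(E) {
  M <- apply(E, 1L, max)
  P <- exp(E - M)
  P / rowSums(P)
}

# ---- layer dispatch ---------------------------------------------------------

CONV_MENU <- list(
  k1 = list(k = 1L, dil = 1L, act = "relu"),
  k3 = list(k = 3L, dil = 1L, act = "relu"),
  k5 = list(k = 5L, dil = 1L, act = "relu"),
  dilated = list(k = 3L, dil = 2L, act = "relu"),
  linear = list(k = 1L, dil = 1L, act = "linear"))

init_conv <- function(option, C, filters) {
  if (option == "inception") {
    lapply(c(1L, 3L, 5L), function(k)
      list(W = matrix(stats::rnorm(k * C * filters, 0,
                                   sqrt(2 / (k * C))), k * C, filters),
           b = numeric(filters)))
  } else {
    m <- CONV_MENU[[option]]
    list(W = matrix(stats::rnorm(m$k * C * filters, 0, sqrt(2 / (m$k * C))),
                    m$k * C, filters),
         b = numeric(filters))
  }
}

conv_out_channels <- function(option, filters)
  if (option == "inception") 3L * filters else filters

layer_fwd <- function(slot, option, params, X, train, drop_rate = NULL) {
  if (identical(option, "identity")) return(list(out = X, cache = NULL))
  if (slot %in% c("conv1", "conv2")) {
    if (option == "inception") {
      ks <- c(1L, 3L, 5L)
      parts <- lapply(seq_along(ks), function(i)
        conv_fwd(X, params[[i]]$W, params[[i]]$b, ks[i], 1L, "relu"))
      out <- array(0, c(dim(X)[1L], dim(X)[2L],
                        sum(vapply(parts, function(p) dim(p$out)[3L], 1L))))
      off <- 0L
      for (p in parts) {
        f <- dim(p$out)[3L]
        out[, , off + seq_len(f)] <- p$out
        off <- off + f
      }
      return(list(out = out, cache = parts))
    }
    m <- CONV_MENU[[option]]
    cc <- conv_fwd(X, params$W, params$b, m$k, m$dil, m$act)
    return(list(out = cc$out, cache = cc))
  }
  if (slot == "dropout") {
    if (!train || drop_rate == 0) return(list(out = X, cache = NULL))
    mask <- array(stats::rbinom(length(X), 1L, 1 - drop_rate) / (1 - drop_rate),
                  dim(X))
    return(list(out = X * mask, cache = mask))
  }
  if (slot == "recurrent") {
    U <- ncol(params$fwd$Wx)
    Hf <- rnn_dir_fwd(X, params$fwd$Wx, params$fwd$Wh, params$fwd$bh, FALSE)
    Hb <- rnn_dir_fwd(X, params$bwd$Wx, params$bwd$Wh, params$bwd$bh, TRUE)
    out <- array(0, c(dim(X)[1L], dim(X)[2L], 2L * U))
    out[, , seq_len(U)] <- Hf; out[, , U + seq_len(U)] <- Hb
    return(list(out = out, cache = list(Hf = Hf, Hb = Hb, X = X, U = U)))
  }
  if (slot == "flatten") {
    n <- dim(X)[1L]
    if (option == "plain")
      return(list(out = matrix(X, n, prod(dim(X)[2:3])), cache = dim(X)))
    if (option == "attention") {
      E <- vapply(seq_len(dim(X)[2L]),
                  function(l) slice2(X, l) %*% params$wa + params$ba,
                  numeric(n))
      E <- matrix(E, n)
      A <- softmax_rows(E)
      out <- matrix(0, n, dim(X)[3L])
      for (l in seq_len(dim(X)[2L]))
        out <- out + A[, l] * slice2(X, l)
      return(list(out = out, cache = list(A = A, X = X)))
    }
    if (option == "dense") {
      Xf <- matrix(X, n, prod(dim(X)[2:3]))
      pre <- Xf %*% params$W + matrix(params$b, n, length(params$b),
                                      byrow = TRUE)
      return(list(out = pmax(pre, 0),
                  cache = list(Xf = Xf, pre = pre, in_dim = dim(X))))
    }
  }
  stop("unknown layer: ", slot, "/", option)
}

layer_bwd <- function(slot, option, params, cache, X, dOut) {
  if (identical(option, "identity")) return(list(dX = dOut, grads = NULL))
  if (slot %in% c("conv1", "conv2")) {
    if (option == "inception") {
      dX <- array(0, dim(X)); grads <- vector("list", 3L); off <- 0L
      for (i in seq_len(3L)) {
        f <- ncol(params[[i]]$W)
        bb <- conv_bwd(cache[[i]], params[[i]]$W, dOut[, , off + seq_len(f)])
        dX <- dX + bb$dX; grads[[i]] <- bb$grads; off <- off + f
      }
      return(list(dX = dX, grads = grads))
    }
    return(conv_bwd(cache, params$W, dOut))
  }
  if (slot == "dropout") {
    if (is.null(cache)) return(list(dX = dOut, grads = NULL))
    return(list(dX = dOut * cache, grads = NULL))
  }
  if (slot == "recurrent") {
    U <- cache$U
    bf <- rnn_dir_bwd(cache$X, cache$Hf, params$fwd$Wx, params$fwd$Wh,
                      dOut[, , seq_len(U), drop = FALSE], FALSE)
    bb <- rnn_dir_bwd(cache$X, cache$Hb, params$bwd$Wx, params$bwd$Wh,
                      dOut[, , U + seq_len(U), drop = FALSE], TRUE)
    return(list(dX = bf$dX + bb$dX,
                grads = list(fwd = list(Wx = bf$dWx, Wh = bf$dWh, bh = bf$dbh),
                             bwd = list(Wx = bb$dWx, Wh = bb$dWh, bh = bb$dbh))))
  }
  if (slot == "flatten") {
    if (option == "plain")
      return(list(dX = array(dOut, cache), grads = NULL))
    if (option == "attention") {
      A <- cache$A; Xa <- cache$X
      n <- dim(Xa)[1L]; L <- dim(Xa)[2L]
      dA <- matrix(0, n, L); dX <- array(0, dim(Xa))
      for (l in seq_len(L)) {
        dA[, l] <- rowSums(dOut * slice2(Xa, l))
        dX[, l, ] <- A[, l] * dOut
      }
      dE <- A * (dA - rowSums(dA * A))
      dwa <- numeric(length(params$wa)); dba <- sum(dE)
      for (l in seq_len(L)) {
        dwa <- dwa + colSums(slice2(Xa, l) * dE[, l])
        dX[, l, ] <- dX[, l, ] + outer(dE[, l], as.numeric(params$wa))
      }
      return(list(dX = dX, grads = list(wa = dwa, ba = dba)))
    }
    if (option == "dense") {
      dpre <- dOut * (cache$pre > 0)
      return(list(dX = array(dpre %*% t(params$W), cache$in_dim),
                  grads = list(W = crossprod(cache$Xf, dpre),
                               b = colSums(dpre))))
    }
  }
  stop("unknown layer: ", slot, "/", option)
}

# ---- transfer model ---------------------------------------------------------

#' Specify a sequence-context backbone
#'
#' The backbone is an ordered menu of layer slots mirroring a small
#' convolutional model space: first convolution (kernel 1/3/5, dilated,
#' inception-like parallel kernels, or a linear positionwise map), an
#' optional second convolution (same menu or identity), dropout
#' (probability searched over a small grid), an optional bidirectional
#' recurrent layer (wide = 32 or narrow = 16 tanh units, or identity), and
#' a flatten layer (plain, attention-pooling, or a 64-unit dense layer).
#' Identity is available in every slot except the first convolution and
#' the flatten.
#'
#' @param conv1 one of \code{"k1","k3","k5","dilated","inception","linear"}.
#' @param conv2 same menu plus \code{"identity"}.
#' @param dropout dropout probability (0 disables).
#' @param recurrent \code{"wide"}, \code{"narrow"}, or \code{"identity"}.
#' @param flatten \code{"plain"}, \code{"attention"}, or \code{"dense"}.
#' @param filters convolution filters per (branch of a) conv layer.
#' @return a named list spec.
#' @export
backbone_spec <- function(conv1 = "k3", conv2 = "identity", dropout = 0.1,
                          recurrent = "identity", flatten = "plain",
                          filters = 16L) {
  stopifnot(conv1 %in% c(names(CONV_MENU), "inception"),
            conv2 %in% c(names(CONV_MENU), "inception", "identity"),
            recurrent %in% c("wide", "narrow", "identity"),
            flatten %in% c("plain", "attention", "dense"),
            dropout >= 0, dropout < 1)
  list(conv1 = conv1, conv2 = conv2, dropout = dropout,
       recurrent = recurrent, flatten = flatten, filters = as.integer(filters))
}

#' Build a transfer model around a frozen pretrained KINN
#'
#' Wraps a pretrained KINN (whose parameters are frozen and
#' fingerprint-checked) with a trainable context backbone. The backbone
#' reads the 25 x 13 alignment encoding and is linearly mapped to one
#' modifier \eqn{\delta} per kinetic rate; the in vivo rates are
#' \eqn{k' = \exp(\kappa + \delta)} where \eqn{\kappa} are the frozen
#' KINN's log rates. The rates pass through the King-Altman and activity
#' layers, and the binary cleavage probability is a sigmoid over an affine
#' map of log activity.
#'
#' @param frozen_kinn a \code{kinn_model} (or list with
#'   \code{architecture}, \code{parameters}) operating on 25 x 13 input.
#' @param spec a \code{\link{backbone_spec}}.
#' @param seed integer seed for backbone initialization.
#' @return object of class \code{"transfer_model"}.
#' @export
transfer_model <- function(frozen_kinn, spec = backbone_spec(), seed = 1L) {
  arch <- frozen_kinn$architecture
  if (arch$input_length != 25L || arch$channels != 13L)
    stop("frozen KINN must operate on the 25 x 13 alignment encoding")
  set.seed(seed)
  C <- 13L; L <- 25L
  params <- list()
  params$conv1 <- init_conv(spec$conv1, C, spec$filters)
  C1 <- conv_out_channels(spec$conv1, spec$filters)
  if (spec$conv2 != "identity") {
    params$conv2 <- init_conv(spec$conv2, C1, spec$filters)
    C2 <- conv_out_channels(spec$conv2, spec$filters)
  } else C2 <- C1
  if (spec$recurrent != "identity") {
    U <- if (spec$recurrent == "wide") 32L else 16L
    rnn_init <- function(Cin) list(
      Wx = matrix(stats::rnorm(Cin * U, 0, sqrt(1 / Cin)), Cin, U),
      Wh = matrix(stats::rnorm(U * U, 0, sqrt(1 / U)), U, U),
      bh = numeric(U))
    params$recurrent <- list(fwd = rnn_init(C2), bwd = rnn_init(C2))
    C3 <- 2L * U
  } else C3 <- C2
  flat_dim <- switch(spec$flatten,
                     plain = L * C3, attention = C3, dense = 64L)
  if (spec$flatten == "attention")
    params$flatten <- list(wa = stats::rnorm(C3, 0, sqrt(1 / C3)), ba = 0)
  if (spec$flatten == "dense")
    params$flatten <- list(
      W = matrix(stats::rnorm(L * C3 * 64L, 0, sqrt(2 / (L * C3))),
                 L * C3, 64L),
      b = numeric(64L))
  E <- nrow(arch$windows)
  params$delta <- list(W = matrix(0, flat_dim, E), b = numeric(E))
  params$out <- list(wo = 1, bo = 0)
  structure(list(frozen = list(architecture = arch,
                               parameters = frozen_kinn$parameters),
                 frozen_fingerprint = param_fingerprint(frozen_kinn$parameters),
                 spec = spec, params = params, seed = seed),
            class = "transfer_model")
}

#' Deterministic fingerprint of a parameter set
#'
#' Used to verify the freeze contract: the frozen KINN's fingerprint must
#' be identical before and after any transfer-training run.
#'
#' @param params any nested list of numeric arrays.
#' @return a character fingerprint.
#' @export
param_fingerprint <- function(params) {
  v <- unlist(params, use.names = FALSE)
  paste(length(v), format(sum(v), digits = 17),
        format(sum(v^2), digits = 17),
        format(sum(v * seq_along(v)), digits = 17), sep = "|")
}

#' Combine frozen log rates with learned modifiers
#'
#' \eqn{k'_e = \exp(\kappa_e + \delta_e)}: the in vitro log rates
#' \eqn{\kappa} shifted by the per-rate in vivo context modifiers.
#'
#' @param kappa named log-rate vector from a frozen KINN.
#' @param delta modifier vector of the same length.
#' @return strictly positive named rate vector.
#' @export
combine_rates <- function(kappa, delta) {
  if (length(kappa) != length(delta))
    stop("kappa and delta must have equal length")
  exp(kappa + delta)
}

transfer_forward <- function(model, X, train = FALSE) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  sp <- model$spec; pp <- model$params
  caches <- list(); cur <- X; ins <- list()
  slots <- list(c("conv1", sp$conv1), c("conv2", sp$conv2),
                c("dropout", "dropout"), c("recurrent", sp$recurrent),
                c("flatten", sp$flatten))
  for (sl in slots) {
    slot <- sl[1L]; option <- sl[2L]
    if (slot == "dropout") option <- "dropout"
    ins[[slot]] <- cur
    r <- if (slot == "dropout")
      layer_fwd(slot, "dropout", NULL, cur, train, drop_rate = sp$dropout)
    else layer_fwd(slot, option, pp[[slot]], cur, train)
    caches[[slot]] <- r$cache
    cur <- r$out
  }
  flat <- cur
  delta <- flat %*% pp$delta$W +
    matrix(pp$delta$b, nrow(flat), length(pp$delta$b), byrow = TRUE)
  arch <- model$frozen$architecture
  kap <- kinn_forward(arch, model$frozen$parameters, X)$logk   # frozen
  logk <- kap + delta
  ka <- ka_activity(arch, logk)
  lognu <- log(pmax(ka$nu, 1e-30))
  z <- pp$out$wo * lognu + pp$out$bo
  p <- stats::plogis(z)
  list(p = p, z = z, lognu = lognu, ka = ka, logk = logk, kappa = kap,
       delta = delta, flat = flat, caches = caches, ins = ins, X = X)
}

# KA steady state + activity for an n x E log-rate matrix (shared by the
# transfer head); returns intermediates for the backward pass
ka_activity <- function(arch, logk) {
  sch <- arch$scheme
  E <- ncol(logk)
  offs <- rep(0, E)
  if (!is.null(sch$binding_edge) && sch$reservoir_concentration > 0)
    offs[match(sch$binding_edge, sch$edges$symbol)] <-
      log(sch$reservoir_concentration)
  logk_eff <- sweep(logk, 2L, -offs)
  dg <- arch$diagrams
  Lw <- logk_eff %*% t(dg$binary_matrix)
  m <- apply(Lw, 1L, max)
  P <- exp(Lw - m)
  pnorm <- P / rowSums(P)
  Tm <- outer(dg$terminal, seq_len(sch$n_states) - 1L, "==") * 1
  s <- pnorm %*% Tm
  aidx <- match(sch$activity_edges, sch$edges$symbol)
  asrc <- sch$edges$from[aidx] + 1L
  kact <- exp(logk_eff[, aidx, drop = FALSE])
  nu <- rowSums(kact * s[, asrc, drop = FALSE])
  list(nu = nu, s = s, pnorm = pnorm, logk_eff = logk_eff,
       aidx = aidx, asrc = asrc, kact = kact)
}

# gradient of activity wrt the log-rate matrix, given dnu (length n)
ka_activity_bwd <- function(arch, ka, dnu) {
  sch <- arch$scheme
  dg <- arch$diagrams
  n <- length(dnu)
  dlogk <- matrix(0, n, ncol(ka$logk_eff))
  ds <- matrix(0, n, sch$n_states)
  for (ii in seq_along(ka$aidx)) {
    e <- ka$aidx[ii]; sA <- ka$asrc[ii]
    dlogk[, e] <- dlogk[, e] + dnu * ka$kact[, ii] * ka$s[, sA]
    ds[, sA] <- ds[, sA] + dnu * ka$kact[, ii]
  }
  G <- ds[, dg$terminal + 1L, drop = FALSE]
  dot <- rowSums(ds * ka$s)
  dLw <- ka$pnorm * (G - dot)
  dlogk + dLw %*% dg$binary_matrix
}

transfer_backward <- function(model, fw, dz) {
  sp <- model$spec; pp <- model$params
  n <- length(dz)
  grads <- list()
  grads$out <- list(wo = sum(dz * fw$lognu), bo = sum(dz))
  dlognu <- dz * pp$out$wo
  dnu <- dlognu / pmax(fw$ka$nu, 1e-30)
  ddelta <- ka_activity_bwd(model$frozen$architecture, fw$ka, dnu)
  grads$delta <- list(W = crossprod(fw$flat, ddelta), b = colSums(ddelta))
  dflat <- ddelta %*% t(pp$delta$W)
  cur <- dflat
  for (slot in c("flatten", "recurrent", "dropout", "conv2", "conv1")) {
    option <- switch(slot, flatten = sp$flatten, recurrent = sp$recurrent,
                     dropout = "dropout", conv2 = sp$conv2, conv1 = sp$conv1)
    r <- layer_bwd(slot, option, pp[[slot]], fw$caches[[slot]],
                   fw$ins[[slot]], cur)
    if (!is.null(r$grads)) grads[[slot]] <- r$grads
    cur <- r$dX
  }
  grads
}

#' Predicted cleavage probability of a transfer model
#'
#' Forward pass in evaluation mode (no dropout); gradient never reaches
#' the frozen KINN parameters, which are re-read untouched on every call.
#'
#' @param model a \code{\link{transfer_model}}.
#' @param x a 25 x 13 encoding or an n x 25 x 13 array.
#' @return probabilities in (0, 1).
#' @export
predict_proba <- function(model, x) {
  if (is.matrix(x) && !identical(dim(x), c(25L, 13L)))
    stop("expected a 25 x 13 encoded alignment")
  transfer_forward(model, x, train = FALSE)$p
}

#' @export
predict.transfer_model <- function(object, x, ...) predict_proba(object, x)

#' @export
print.transfer_model <- function(x, ...) {
  sp <- x$spec
  cat("Transfer model: frozen", x$frozen$architecture$scheme$n_states,
      "state KINN +", sp$conv1,
      if (sp$conv2 != "identity") paste0("-> ", sp$conv2) else "",
      "backbone, dropout", sp$dropout, ", recurrent", sp$recurrent,
      ", flatten", sp$flatten, "\n")
  cat("frozen fingerprint:", x$frozen_fingerprint, "\n")
  invisible(x)
}
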