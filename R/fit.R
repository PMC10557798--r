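#' Training configuration for a KINN
#'
#' @param epochs maximum full-batch Adam epochs.
#' @param lr learning rate.
#' @param loss \code{"log_mse"} (mean squared error on log cleavage rate;
#'   the default, since labels span decades) or \code{"mse"} on the linear
#'   scale.
#' @param seed integer seed controlling initialization (and any sampling).
#' @param patience early-stopping patience in epochs, judged on validation
#'   Pearson when validation data are supplied (otherwise on training
#'   loss).
#' @param init_sd kernel initialization s.d.
#' @return a list of class \code{"train_config"}.
#' @export
train_config <- function(epochs = 300L, lr = 0.05, loss = c("log_mse", "mse"),
                         seed = 1L, patience = 30L, init_sd = 0.05) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, lr > 0, patience >= 1L)
  structure(list(epochs = as.integer(epochs), lr = lr, loss = loss,
                 seed = as.integer(seed), patience = as.integer(patience),
                 init_sd = init_sd),
            class = "train_config")
}

loss_grad <- function(pred, y, loss, eps = 1e-12) {
  n <- length(y)
  if (loss == "log_mse") {
    pc <- pmax(pred, eps)
    d <- log(pc) - log(y)
    list(loss = mean(d^2),
         dy = ifelse(pred > eps, 2 * d / (n * pc), 0))
  } else {
    list(loss = mean((pred - y)^2), dy = 2 * (pred - y) / n)
  }
}

adam_step <- function(state, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  state$x <- state$x - lr * mh / (sqrt(vh) + eps)
  state
}

#' Fit a KINN to measured cleavage rates
#'
#' Full-batch Adam on the selected loss. All randomness (parameter
#' initialization) is governed by the config seed, so two runs with the
#' same inputs give bitwise-identical histories. When validation data are
#' supplied, training early-stops on validation Pearson and the
#' best-validation parameters are restored.
#'
#' @param arch a \code{\link{kinn_architecture}}.
#' @param x encoded inputs, an \code{n x L x channels} array.
#' @param y positive cleavage-rate labels, length n.
#' @param validation optional \code{list(x = , y = )} held-out set.
#' @param config a \code{\link{train_config}}.
#' @param init optional starting \code{kinn_parameters}.
#' @return an object of class \code{"kinn_model"}: list with
#'   \code{architecture}, \code{parameters}, \code{history} (data.frame
#'   epoch/loss/val_pearson), \code{config}, \code{fitted.values},
#'   \code{y}.
#' @export
kinn_fit <- function(arch, x, y, validation = NULL, config = train_config(),
                     init = NULL) {
  y <- as.numeric(y)
  if (config$loss == "log_mse" && any(y <= 0))
    stop("log-scale loss requires strictly positive labels")
  feats <- kinn_features(arch, x)
  vfeats <- if (!is.null(validation)) kinn_features(arch, validation$x)
  params <- if (is.null(init))
    kinn_init(arch, labels = y, init_sd = config$init_sd, seed = config$seed)
  else init
  flat <- params_pack(params)
  ad <- list(x = flat, m = numeric(length(flat)), v = numeric(length(flat)),
             t = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_pearson = numeric())
  best <- list(score = -Inf, flat = flat, wait = 0L)
  best_loss <- Inf; wait_loss <- 0L
  const_warned <- FALSE
  for (ep in seq_len(config$epochs)) {
    params <- params_unpack(ad$x, params)
    fw <- kinn_forward(arch, params, feats)
    lg <- loss_grad(fw$y, y, config$loss)
    grad <- kinn_backward(arch, params, fw, lg$dy)
    if (!isTRUE(arch$link$trainable)) {
      nlink <- 3L * arch$link$hidden + 1L
      grad[(length(grad) - nlink + 1L):length(grad)] <- 0
    }
    ad <- adam_step(ad, grad, config$lr)
    vp <- NA_real_
    if (!is.null(validation)) {
      pv <- kinn_forward(arch, params, vfeats)$y
      vp <- if (stats::sd(pv) == 0 || stats::sd(validation$y) == 0) {
        if (!const_warned) {
          warning("constant predictions; validation Pearson undefined, using 0")
          const_warned <- TRUE
        }
        0
      } else stats::cor(log(pmax(pv, 1e-12)), log(pmax(validation$y, 1e-12)))
      if (is.na(vp)) vp <- 0
      score <- vp
    } else score <- -lg$loss
    hist <- rbind(hist, data.frame(epoch = ep, loss = lg$loss,
                                   val_pearson = vp))
    if (lg$loss < best_loss * (1 - 1e-4)) {
      best_loss <- lg$loss; wait_loss <- 0L
    } else wait_loss <- wait_loss + 1L
    if (score > best$score) {
      best$score <- score; best$flat <- params_pack(params); best$wait <- 0L
    } else {
      best$wait <- best$wait + 1L
      # validation scores can dip while optimization still progresses, so
      # stop only once the training loss has stalled as well
      if (best$wait >= config$patience && wait_loss >= config$patience) break
    }
  }
  params <- params_unpack(best$flat, params)
  fitted <- kinn_forward(arch, params, feats)$y
  structure(list(architecture = arch, parameters = params, history = hist,
                 config = config, fitted.values = fitted, y = y,
                 call = match.call()),
            class = "kinn_model")
}

#' @export
predict.kinn_model <- function(object, x,
                               type = c("response", "log_rates", "occupancy"),
                               ...) {
  type <- match.arg(type)
  fw <- kinn_forward(object$architecture, object$parameters, x)
  out <- switch(type, response = fw$y, log_rates = fw$logk, occupancy = fw$s)
  if (!is.null(dim(out)) && nrow(out) == 1L && type != "response") out[1L, ]
  else out
}

#' @export
print.kinn_model <- function(x, ...) {
  cat("KINN:", x$architecture$scheme$n_states, "states,",
      nrow(x$architecture$windows), "rate windows,",
      length(params_pack(x$parameters)), "parameters;",
      x$architecture$output_head, "head\n")
  cat("trained", nrow(x$history), "epochs; final loss",
      signif(utils::tail(x$history$loss, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.kinn_model <- function(object, ...) {
  h <- object$history
  res <- list(windows = object$architecture$windows,
              n_parameters = length(params_pack(object$parameters)),
              epochs = nrow(h),
              final_loss = utils::tail(h$loss, 1),
              best_val_pearson = suppressWarnings(max(h$val_pearson, na.rm = TRUE)),
              train_pearson = suppressWarnings(
                pearson_fitness(log(pmax(object$fitted.values, 1e-12)),
                                log(pmax(object$y, 1e-12)))))
  class(res) <- "summary.kinn_model"
  res
}

#' @export
print.summary.kinn_model <- function(x, ...) {
  cat("KINN fit:", x$n_parameters, "parameters,", x$epochs, "epochs\n")
  cat("final training loss:", signif(x$final_loss, 4),
      "; training log-Pearson:", signif(x$train_pearson, 4), "\n")
  if (is.finite(x$best_val_pearson))
    cat("best validation Pearson:", signif(x$best_val_pearson, 4), "\n")
  cat("rate windows:\n"); print(x$windows, row.names = FALSE)
  invisible(x)
}

#' @export
coef.kinn_model <- function(object, ...) {
  p <- params_pack(object$parameters)
  names(p) <- flat_param_names(object$architecture)
  p
}

#' @export
residuals.kinn_model <- function(object, ...) {
  if (object$config$loss == "log_mse")
    log(pmax(object$fitted.values, 1e-12)) - log(object$y)
  else object$fitted.values - object$y
}

flat_param_names <- function(arch) {
  nm <- character()
  for (e in seq_len(nrow(arch$windows))) {
    s <- arch$windows$symbol[e]; d <- arch$windows$kernel[e]
    C <- arch$channels
    nm <- c(nm, paste0(s, "_W", rep(seq_len(d), C), "_",
                       rep(seq_len(C), each = d)), paste0(s, "_b"))
  }
  h <- arch$link$hidden
  c(nm, paste0("Wt", seq_len(h)), paste0("bt", seq_len(h)),
    paste0("Wo", seq_len(h)), "bo")
}

#' Gradient of the KINN prediction for one input
#'
#' Analytic gradient of \code{predict} with respect to every parameter, in
#' the flat packing order used by \code{\link{coef.kinn_model}}. The
#' training contract is that this agrees with central finite differences;
#' both output heads are differentiable (the eigen head through
#' left/right-eigenvector perturbation theory of the slow mode).
#'
#' @param arch a \code{\link{kinn_architecture}}.
#' @param params \code{kinn_parameters}.
#' @param x a single encoded input (L x channels matrix).
#' @return named numeric gradient vector.
#' @export
kinn_predict_gradient <- function(arch, params, x) {
  fw <- kinn_forward(arch, params, x)
  g <- kinn_backward(arch, params, fw, 1)
  names(g) <- flat_param_names(arch)
  g
}
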