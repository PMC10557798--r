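zero_like <- function(x) rapply(x, function(v) v * 0, how = "replace")

unpack_like <- function(flat, template) {
  pos <- 1L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    k <- length(x)
    v <- flat[pos:(pos + k - 1L)]
    pos <<- pos + k
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  fill(template)
}

grads_to_flat <- function(params, grads) {
  g <- params
  for (nm in names(g))
    g[[nm]] <- if (!is.null(grads[[nm]])) grads[[nm]] else zero_like(g[[nm]])
  unlist(g, use.names = FALSE)
}

#' Transfer-training configuration
#'
#' @param epochs maximum epochs of minibatch Adam.
#' @param batch_size minibatch size.
#' @param lr learning rate.
#' @param patience early-stopping patience (epochs) on validation average
#'   precision.
#' @param pos_weight positive-class loss weight; \code{"auto"} uses the
#'   negative/positive count ratio of the training labels (rare positives
#'   dominate real off-target compilations).
#' @param seed integer seed (shuffling, dropout, initialization all follow
#'   it).
#' @return a list of class \code{"transfer_config"}.
#' @export
transfer_config <- function(epochs = 12L, batch_size = 128L, lr = 2e-3,
                            patience = 4L, pos_weight = "auto", seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "transfer_config")
}

#' Train a transfer model on binary cleavage labels
#'
#' Minimizes class-weighted binary cross-entropy with minibatch Adam;
#' gradient flows through the context backbone, the modifier head and the
#' output head only -- the frozen KINN parameters are fingerprint-checked
#' before and after training. Validation average precision is recorded per
#' epoch, with early stopping and best-epoch restoration.
#'
#' @param model a \code{\link{transfer_model}}.
#' @param train,val lists with \code{X} (n x 25 x 13 array) and binary
#'   \code{y}.
#' @param config a \code{\link{transfer_config}}.
#' @return the trained \code{transfer_model} with a \code{history}
#'   data.frame (epoch, loss, val_ap) attached.
#' @export
fit_transfer <- function(model, train, val, config = transfer_config()) {
  y <- as.numeric(train$y)
  if (length(unique(y)) < 2L)
    stop("training labels are single-class; cannot fit a classifier")
  fp0 <- param_fingerprint(model$frozen$parameters)
  set.seed(config$seed)
  wp <- if (identical(config$pos_weight, "auto")) sum(y == 0) / sum(y == 1)
        else config$pos_weight
  n <- length(y)
  flat <- unlist(model$params, use.names = FALSE)
  ad <- list(x = flat, m = numeric(length(flat)), v = numeric(length(flat)),
             t = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_ap = numeric())
  best <- list(ap = -Inf, flat = flat, wait = 0L)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      model$params <- unpack_like(ad$x, model$params)
      fw <- transfer_forward(model, train$X[b, , , drop = FALSE],
                             train = TRUE)
      yb <- y[b]
      wv <- ifelse(yb == 1, wp, 1)
      pc <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      loss <- -sum(wv * (yb * log(pc) + (1 - yb) * log(1 - pc))) / sum(wv)
      dz <- wv * (fw$p - yb) / sum(wv)
      grads <- transfer_backward(model, fw, dz)
      ad <- adam_step(ad, grads_to_flat(model$params, grads), config$lr)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    model$params <- unpack_like(ad$x, model$params)
    pv <- transfer_forward(model, val$X, train = FALSE)$p
    ap <- average_precision(pv, val$y)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_ap = ap))
    if (ap > best$ap) {
      best$ap <- ap; best$flat <- ad$x; best$wait <- 0L
    } else {
      best$wait <- best$wait + 1L
      if (best$wait >= config$patience) break
    }
  }
  model$params <- unpack_like(best$flat, model$params)
  if (!identical(param_fingerprint(model$frozen$parameters), fp0))
    stop("freeze contract violated: frozen KINN parameters changed")
  model$history <- hist
  model$config <- config
  model
}

#' Discrete model space for transfer-architecture selection
#'
#' @param kinns list of candidate frozen pretrained KINNs (e.g. several
#'   state counts x source datasets).
#' @param conv1,conv2,dropout,recurrent,flatten candidate options per
#'   backbone slot; identity is available everywhere except the first
#'   convolution and the flatten.
#' @return a list of class \code{"model_space"}.
#' @export
model_space <- function(kinns,
                        conv1 = c("k1", "k3", "k5", "dilated", "inception",
                                  "linear"),
                        conv2 = c("k1", "k3", "k5", "dilated", "inception",
                                  "linear", "identity"),
                        dropout = c(0.1, 0.3, 0.5),
                        recurrent = c("wide", "narrow", "identity"),
                        flatten = c("plain", "attention", "dense")) {
  if (!is.list(kinns) || !length(kinns)) stop("kinns must be a nonempty list")
  slots <- list(conv1 = conv1, conv2 = conv2, dropout = dropout,
                recurrent = recurrent, flatten = flatten,
                kinn = seq_along(kinns))
  if (any(!vapply(slots, length, 1L)))
    stop("every slot needs at least one option")
  structure(list(slots = slots, kinns = kinns), class = "model_space")
}

#' Random search over the transfer model space
#'
#' Samples (backbone, pretrained-KINN) combinations uniformly from the
#' discrete space, trains each briefly, and ranks them by validation
#' average precision. Returns the best model, per-slot selection
#' frequencies among the top models, and the top-n models as an ensemble
#' whose prediction is the mean probability.
#'
#' @param space a \code{\link{model_space}}.
#' @param train,val lists with \code{X} and binary \code{y}.
#' @param budget number of combinations to evaluate (\eqn{\ge 1}).
#' @param config per-candidate \code{\link{transfer_config}}.
#' @param seed integer seed.
#' @param top_n ensemble / frequency-summary size.
#' @return object of class \code{"transfer_selection"}: \code{best_model},
#'   \code{results} (one row per candidate), \code{frequencies} (per-slot,
#'   over the top models), \code{ensemble} (list of trained models).
#' @export
select_model <- function(space, train, val, budget = 20L,
                         config = transfer_config(epochs = 6L, patience = 3L),
                         seed = 1L, top_n = 5L) {
  if (budget < 1L) stop("budget must be at least 1")
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i)
    lapply(space$slots, function(opts) opts[sample.int(length(opts), 1L)]))
  results <- list(); models <- list()
  for (i in seq_len(budget)) {
    d <- draws[[i]]
    sp <- backbone_spec(conv1 = d$conv1, conv2 = d$conv2,
                        dropout = as.numeric(d$dropout),
                        recurrent = d$recurrent, flatten = d$flatten)
    cfg <- config; cfg$seed <- seed * 1000L + i
    tm <- transfer_model(space$kinns[[d$kinn]], sp, seed = cfg$seed)
    tm <- fit_transfer(tm, train, val, cfg)
    ap <- max(tm$history$val_ap)
    models[[i]] <- tm
    results[[i]] <- data.frame(candidate = i, conv1 = d$conv1,
                               conv2 = d$conv2, dropout = d$dropout,
                               recurrent = d$recurrent, flatten = d$flatten,
                               kinn = d$kinn, val_ap = ap)
  }
  res <- do.call(rbind, results)
  ord <- order(-res$val_ap, res$candidate)
  top <- res[ord[seq_len(min(top_n, nrow(res)))], ]
  freqs <- lapply(names(space$slots), function(sl) {
    tab <- table(factor(as.character(top[[sl]]),
                        levels = as.character(space$slots[[sl]])))
    tab / sum(tab)
  })
  names(freqs) <- names(space$slots)
  structure(list(best_model = models[[ord[1L]]], results = res,
                 frequencies = freqs,
                 ensemble = models[ord[seq_len(min(top_n, nrow(res)))]],
                 seed = seed),
            class = "transfer_selection")
}

#' Mean-probability prediction of a transfer-model ensemble
#'
#' @param models list of trained \code{\link{transfer_model}}s.
#' @param x encoded input array.
#' @return averaged probabilities.
#' @export
ensemble_predict <- function(models, x) {
  ps <- vapply(models, function(m) predict_proba(m, x),
               numeric(if (is.matrix(x)) 1L else dim(x)[1L]))
  rowMeans(matrix(ps, ncol = length(models)))
}

#' @export
print.transfer_selection <- function(x, ...) {
  cat("Transfer model selection:", nrow(x$results),
      "candidates; best validation AP =",
      signif(max(x$results$val_ap), 4), "\n")
  for (sl in names(x$frequencies)) {
    f <- x$frequencies[[sl]]
    cat(" ", sl, ":", paste(names(f), round(as.numeric(f), 2),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
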