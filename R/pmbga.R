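#' Anchor position for a kinetic rate on the input sequence
#'
#' The anchor function uniformly maps each rate of an n-state scheme onto
#' the input sequence: the forward rate \eqn{k_{\alpha,\alpha+1}} is
#' anchored at \eqn{\mathrm{round}(L (\alpha + 1) / n)}. A backward rate
#' inherits its forward partner's anchor; a cycle-closing edge (such as the
#' cut step \eqn{k_{30}}) is anchored by its origin state like a forward
#' rate. For a four-state scheme on a 20-bp input this places
#' \eqn{k_{01}, k_{12}, k_{23}} at positions 5, 10 and 15.
#'
#' @param rate_symbol edge symbol, e.g. \code{"k12"}.
#' @param n_states number of scheme states.
#' @param input_length encoded input length L (\code{>= n_states}).
#' @return integer anchor position.
#' @export
anchor_position <- function(rate_symbol, n_states, input_length) {
  if (input_length < n_states)
    stop("input_length must be at least n_states")
  ft <- parse_rate_symbols(rate_symbol)
  a <- ft$from; b <- ft$to
  if (a >= n_states || b >= n_states)
    stop("rate ", rate_symbol, " does not belong to an ", n_states,
         "-state scheme")
  origin <- if (b == a + 1L) a           # forward step
    else if (a == b + 1L) b              # backward: partner's anchor
    else max(a, b)                       # cycle-closing / long-range edge
  as.integer(floor(input_length * (origin + 1) / n_states + 0.5))
}

#' Architecture prior for the probabilistic genetic algorithm
#'
#' Per rate, three categorical distributions: window start \eqn{i} over the
#' integer interval \eqn{[\phi(k) - w/2, \phi(k) + w/2]} (clipped to valid
#' positions), window length \eqn{j - i} over \eqn{[1, 5]}, and kernel size
#' \eqn{d} over \eqn{[1, 5]} (truncated to \eqn{[1, j-i]} at sampling
#' time). All start uniform (Dirichlet concentration 1 per cell) and are
#' updated by survivor pseudo-counts.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param input_length encoded input length.
#' @param channels encoding channels.
#' @param w search window half-range (support width; default 10).
#' @param max_len maximum window length (default 5).
#' @param output_head,link passed through to sampled architectures.
#' @return object of class \code{"architecture_prior"}.
#' @export
architecture_prior <- function(scheme, input_length, channels = 4L, w = 10L,
                               max_len = 5L,
                               output_head = "ka_steady_state",
                               link = kinn_link()) {
  per_edge <- lapply(scheme$edges$symbol, function(s) {
    phi <- anchor_position(s, scheme$n_states, input_length)
    hi <- min(input_length - 1L, as.integer(phi + w / 2))
    lo <- max(0L, min(as.integer(phi - w / 2), hi))
    if (lo > hi) stop("empty start support for ", s)
    list(start = list(support = lo:hi, alpha = rep(1, hi - lo + 1L)),
         len   = list(support = seq_len(max_len), alpha = rep(1, max_len)),
         kernel = list(support = seq_len(max_len), alpha = rep(1, max_len)))
  })
  names(per_edge) <- scheme$edges$symbol
  structure(list(per_edge = per_edge, scheme = scheme,
                 input_length = as.integer(input_length),
                 channels = as.integer(channels),
                 output_head = output_head, link = link),
            class = "architecture_prior")
}

prior_probs <- function(cat) cat$alpha / sum(cat$alpha)

sample_categorical <- function(cat, keep = NULL) {
  sup <- cat$support; p <- prior_probs(cat)
  if (!is.null(keep)) {
    ok <- keep(sup)
    if (!any(ok)) stop("empty categorical support after truncation")
    sup <- sup[ok]; p <- p[ok] / sum(p[ok])
  }
  sup[sample.int(length(sup), 1L, prob = p)]
}

#' Sample a KINN architecture from a prior
#'
#' Draws one window spec per rate; window length and kernel size are
#' truncated so the sampled spec is always valid (window inside the input,
#' kernel no longer than the window).
#'
#' @param prior an \code{\link{architecture_prior}}.
#' @return a \code{\link{kinn_architecture}} with attribute
#'   \code{"choices"} recording the sampled categories (used by the
#'   posterior update).
#' @export
sample_architecture <- function(prior) {
  L <- prior$input_length
  rows <- lapply(names(prior$per_edge), function(s) {
    pe <- prior$per_edge[[s]]
    i <- sample_categorical(pe$start, keep = function(v) v <= L - 1L)
    len <- sample_categorical(pe$len, keep = function(v) v <= L - i)
    d <- sample_categorical(pe$kernel, keep = function(v) v <= len)
    data.frame(symbol = s, start = i, end = i + len, kernel = d)
  })
  win <- do.call(rbind, rows)
  arch <- kinn_architecture(prior$scheme, win, L, prior$channels,
                            output_head = prior$output_head,
                            link = prior$link)
  attr(arch, "choices") <- win
  arch
}

#' Fitness of an architecture: validation Pearson after training
#'
#' Fits the KINN on the training set and scores the Pearson correlation of
#' prediction vs observation on the disjoint validation set (log scale for
#' the default log-loss). Constant predictions give fitness 0.
#'
#' @param arch a \code{\link{kinn_architecture}}.
#' @param train,val lists with \code{x} (encoded array) and \code{y}.
#' @param config a \code{\link{train_config}}.
#' @return list with \code{fitness} and the fitted \code{model}.
#' @export
evaluate_fitness <- function(arch, train, val, config = train_config()) {
  model <- kinn_fit(arch, train$x, train$y, validation = val, config = config)
  pv <- predict(model, val$x)
  fit <- suppressWarnings(
    pearson_fitness(log(pmax(pv, 1e-12)), log(pmax(val$y, 1e-12))))
  if (is.na(fit)) fit <- 0
  list(fitness = fit, model = model)
}

#' Dirichlet-categorical posterior update from survivors
#'
#' Adds one pseudo-count per survivor to each categorical cell the survivor
#' chose (start, length, kernel size, per rate) and renormalizes.
#'
#' @param prior an \code{\link{architecture_prior}}.
#' @param survivors list of architectures (with \code{"choices"}
#'   attributes) that outperformed the generation's expected fitness.
#' @return the updated prior.
#' @export
update_posterior <- function(prior, survivors) {
  for (arch in survivors) {
    ch <- attr(arch, "choices")
    for (r in seq_len(nrow(ch))) {
      s <- ch$symbol[r]
      pe <- prior$per_edge[[s]]
      ii <- match(ch$start[r], pe$start$support)
      il <- match(ch$end[r] - ch$start[r], pe$len$support)
      id <- match(ch$kernel[r], pe$kernel$support)
      if (!is.na(ii)) pe$start$alpha[ii] <- pe$start$alpha[ii] + 1
      if (!is.na(il)) pe$len$alpha[il] <- pe$len$alpha[il] + 1
      if (!is.na(id)) pe$kernel$alpha[id] <- pe$kernel$alpha[id] + 1
      prior$per_edge[[s]] <- pe
    }
  }
  prior
}

#' Probabilistic model-building genetic-algorithm search over KINNs
#'
#' Runs the sample - train - select - update loop: each generation samples
#' \code{pop} architectures from the current prior, trains and scores each
#' (validation Pearson), computes the generation's expected fitness
#' \eqn{C_t} (its mean fitness), keeps the architectures with fitness
#' strictly above \eqn{C_t} (falling back to the top half, deterministic
#' index tie-break, when none exceed the mean), and applies the
#' Dirichlet-categorical posterior update. With \code{adapt = FALSE} the
#' prior is never updated, giving the matched-budget random-sampling
#' baseline.
#'
#' @param prior an \code{\link{architecture_prior}}.
#' @param train,val lists with \code{x}, \code{y} (disjoint; split by guide
#'   upstream).
#' @param generations,pop search budget (default 10 x 10).
#' @param config per-architecture \code{\link{train_config}} (budgeted:
#'   few epochs, early stopping).
#' @param seed integer seed for the whole search.
#' @param adapt logical; \code{FALSE} freezes the prior (random search).
#' @return object of class \code{"kinn_search"}: \code{best_model},
#'   \code{best_arch}, \code{best_fitness}, \code{posterior},
#'   \code{history} (per generation: mean, max, best-so-far fitness) and
#'   \code{evaluations} (one row per trained architecture).
#' @export
kinn_search <- function(prior, train, val, generations = 10L, pop = 10L,
                        config = train_config(epochs = 80L, patience = 8L),
                        seed = 1L, adapt = TRUE) {
  stopifnot(generations >= 1L, pop >= 2L)
  set.seed(seed)
  hist <- data.frame(generation = integer(), mean_fitness = numeric(),
                     max_fitness = numeric(), best_so_far = numeric())
  evals <- list()
  best <- list(fitness = -Inf, model = NULL, arch = NULL)
  n_fail <- 0L
  for (g in seq_len(generations)) {
    archs <- replicate(pop, sample_architecture(prior), simplify = FALSE)
    fits <- numeric(pop)
    for (i in seq_len(pop)) {
      config$seed <- seed * 10000L + g * 100L + i   # deterministic per fit
      res <- tryCatch(evaluate_fitness(archs[[i]], train, val, config),
                      error = function(e) NULL)
      if (is.null(res)) { fits[i] <- NA_real_; n_fail <- n_fail + 1L; next }
      fits[i] <- res$fitness
      if (res$fitness > best$fitness)
        best <- list(fitness = res$fitness, model = res$model,
                     arch = archs[[i]])
      w <- archs[[i]]$windows
      evals[[length(evals) + 1L]] <- data.frame(
        generation = g, member = i, fitness = res$fitness,
        spec = paste(sprintf("%s:%d-%d/%d", w$symbol, w$start, w$end,
                             w$kernel), collapse = " "))
    }
    if (all(is.na(fits)))
      stop("all architecture fits failed in generation ", g)
    Ct <- mean(fits, na.rm = TRUE)
    surv <- which(!is.na(fits) & fits > Ct)
    if (!length(surv)) {
      ord <- order(-fits, seq_along(fits), na.last = TRUE)
      surv <- ord[seq_len(ceiling(pop / 2))]
      surv <- surv[!is.na(fits[surv])]
    }
    if (adapt) prior <- update_posterior(prior, archs[surv])
    hist <- rbind(hist, data.frame(generation = g, mean_fitness = Ct,
                                   max_fitness = max(fits, na.rm = TRUE),
                                   best_so_far = best$fitness))
  }
  structure(list(best_model = best$model, best_arch = best$arch,
                 best_fitness = best$fitness, posterior = prior,
                 history = hist, evaluations = do.call(rbind, evals),
                 seed = seed, adapt = adapt),
            class = "kinn_search")
}

#' @export
print.kinn_search <- function(x, ...) {
  cat("KINN architecture search:", nrow(x$history), "generations,",
      nrow(x$evaluations), "architectures trained",
      if (x$adapt) "(adaptive prior)" else "(frozen prior / random)", "\n")
  cat("best validation fitness:", signif(x$best_fitness, 4), "\n")
  if (!is.null(x$best_arch)) print(x$best_arch$windows, row.names = FALSE)
  invisible(x)
}
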