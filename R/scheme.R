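#' Define a linear kinetic scheme
#'
#' A kinetic scheme is a directed graph of enzymatic states. Each edge
#' \eqn{\alpha \to \beta} carries a rate symbol \code{k<alpha><beta>} (states
#' are 0-indexed). A subset of edges may be flagged as activity-producing:
#' their flux is the experimentally measurable quantity. One edge may be
#' flagged as the reservoir-binding edge; its rate is multiplied by the
#' reservoir concentration (e.g. the unbound-DNA concentration, in nMol)
#' wherever effective rates are used.
#'
#' @param n_states positive integer, number of enzymatic states.
#' @param edges a two-column matrix/data.frame of 0-based \code{from}, \code{to}
#'   state indices, or a character vector of symbols such as \code{"k01"}
#'   (single-digit state labels).
#' @param activity_edges character vector of edge symbols whose flux is
#'   measurable; must be a subset of the scheme's edges.
#' @param reservoir_concentration nonnegative scalar multiplying the binding
#'   edge's rate (default 1).
#' @param binding_edge symbol of the reservoir-binding edge, or \code{NULL}.
#' @return An object of class \code{"kinetic_scheme"}: a list with elements
#'   \code{n_states}, \code{edges} (data.frame \code{from}, \code{to},
#'   \code{symbol}), \code{activity_edges}, \code{reservoir_concentration},
#'   \code{binding_edge}.
#' @examples
#' sc <- kinetic_scheme(3, c("k01", "k10", "k12", "k21"),
#'                      activity_edges = "k12")
#' @export
kinetic_scheme <- function(n_states, edges, activity_edges = character(),
                           reservoir_concentration = 1, binding_edge = NULL) {
  stopifnot(length(n_states) == 1L, n_states >= 2L)
  n_states <- as.integer(n_states)
  if (is.character(edges)) {
    ft <- parse_rate_symbols(edges)
  } else {
    ft <- as.data.frame(edges)[, 1:2]
    names(ft) <- c("from", "to")
    ft$symbol <- paste0("k", ft$from, ft$to)
  }
  ft$from <- as.integer(ft$from); ft$to <- as.integer(ft$to)
  if (any(ft$from == ft$to))
    stop("self-edges are not allowed in a kinetic scheme")
  if (any(ft$from < 0L | ft$from >= n_states | ft$to < 0L | ft$to >= n_states))
    stop("edge endpoints must be states in 0..", n_states - 1L)
  if (anyDuplicated(ft$symbol))
    stop("duplicated edge symbols")
  if (!all(activity_edges %in% ft$symbol))
    stop("activity_edges must be a subset of the scheme's edges")
  if (!is.null(binding_edge) && !binding_edge %in% ft$symbol)
    stop("binding_edge '", binding_edge, "' is not an edge of the scheme")
  if (!is.numeric(reservoir_concentration) || reservoir_concentration < 0)
    stop("reservoir_concentration must be a nonnegative scalar")
  structure(list(n_states = n_states,
                 edges = ft,
                 activity_edges = as.character(activity_edges),
                 reservoir_concentration = as.numeric(reservoir_concentration),
                 binding_edge = binding_edge),
            class = "kinetic_scheme")
}

parse_rate_symbols <- function(symbols) {
  m <- regmatches(symbols, regexec("^k([0-9])([0-9])$", symbols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("cannot parse rate symbol(s): ", paste(symbols[bad], collapse = ", "),
         " (expected 'k<from><to>' with single-digit states)")
  data.frame(from = as.integer(vapply(m, `[`, "", 2L)),
             to   = as.integer(vapply(m, `[`, "", 3L)),
             symbol = symbols, stringsAsFactors = FALSE)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", x$n_states, "states,", nrow(x$edges), "edges\n")
  cat("  edges:", paste(x$edges$symbol, collapse = " "), "\n")
  if (length(x$activity_edges))
    cat("  activity edges:", paste(x$activity_edges, collapse = " "), "\n")
  if (!is.null(x$binding_edge))
    cat("  binding edge:", x$binding_edge,
        "(reservoir =", x$reservoir_concentration, "nMol)\n")
  invisible(x)
}

#' The four-state Cas9 cleavage cycle
#'
#' Convenience constructor for the canonical four-state Cas9 scheme:
#' unbound \eqn{s_0}, PAM-bound \eqn{s_1}, R-loop \eqn{s_2}, cleavage-competent
#' \eqn{s_3}, with reversible steps along the cycle and an irreversible cut
#' \eqn{s_3 \to s_0} producing the measurable cleaved product. The binding
#' step \eqn{s_0 \to s_1} is scaled by the unbound-DNA reservoir
#' concentration \code{Du}.
#'
#' @param Du reservoir concentration in nMol (default 1).
#' @return a \code{\link{kinetic_scheme}}.
#' @export
cas9_scheme <- function(Du = 1) {
  kinetic_scheme(4L,
                 c("k01", "k10", "k12", "k21", "k23", "k32", "k30"),
                 activity_edges = "k30",
                 reservoir_concentration = Du,
                 binding_edge = "k01")
}

#' Validate a rate assignment against a scheme
#'
#' A rate assignment is a named numeric vector mapping every edge symbol of a
#' scheme to a strictly positive, finite rate constant (units s^-1, or
#' s^-1 nMol^-1 for the binding edge).
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param rates named numeric vector.
#' @return the rates, reordered to the scheme's edge order.
#' @export
validate_rates <- function(scheme, rates) {
  sym <- scheme$edges$symbol
  missing <- setdiff(sym, names(rates))
  if (length(missing))
    stop("missing rate(s): ", paste(missing, collapse = ", "))
  r <- as.numeric(rates[sym]); names(r) <- sym
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all rates must be strictly positive and finite")
  r
}

# rates with the binding edge scaled by the reservoir concentration
effective_rates <- function(scheme, rates) {
  r <- validate_rates(scheme, rates)
  if (!is.null(scheme$binding_edge))
    r[scheme$binding_edge] <- r[scheme$binding_edge] * scheme$reservoir_concentration
  r
}

#' Test strong connectivity of a scheme
#'
#' Every state must be reachable from every other along directed edges for
#' the King-Altman steady state to exist.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @return logical; attribute \code{"unreachable"} names offending states when
#'   \code{FALSE}.
#' @export
is_strongly_connected <- function(scheme) {
  n <- scheme$n_states
  adj <- lapply(seq_len(n) - 1L, function(s) scheme$edges$to[scheme$edges$from == s])
  radj <- lapply(seq_len(n) - 1L, function(s) scheme$edges$from[scheme$edges$to == s])
  reach <- function(a, start) {
    seen <- logical(n); seen[start + 1L] <- TRUE; stack <- start
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (w in a[[v + 1L]]) if (!seen[w + 1L]) { seen[w + 1L] <- TRUE; stack <- c(stack, w) }
    }
    seen
  }
  fwd <- reach(adj, 0L); bwd <- reach(radj, 0L)
  ok <- all(fwd & bwd)
  if (!ok) attr(ok, "unreachable") <- which(!(fwd & bwd)) - 1L
  ok
}

#' Generate a random strongly connected kinetic scheme
#'
#' Builds a reversible cycle through all states (which guarantees strong
#' connectivity), then adds further random edges with probability
#' \code{p_extra} each. Used for property sweeps and benchmarking; the
#' cycle-closing edge is flagged as the activity edge.
#'
#' @param n_states number of states (3--6 is the intended range).
#' @param p_extra probability of including each additional off-cycle edge.
#' @return a \code{\link{kinetic_scheme}}.
#' @export
random_scheme <- function(n_states, p_extra = 0.2) {
  n <- as.integer(n_states)
  fwd <- cbind(0:(n - 1L), c(1:(n - 1L), 0L))
  bwd <- fwd[, 2:1]
  ft <- rbind(fwd, bwd)
  all_pairs <- expand.grid(from = 0:(n - 1L), to = 0:(n - 1L))
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  key <- paste(ft[, 1], ft[, 2]); pkey <- paste(all_pairs$from, all_pairs$to)
  extra <- all_pairs[!(pkey %in% key), , drop = FALSE]
  take <- stats::runif(nrow(extra)) < p_extra
  ft <- rbind(ft, as.matrix(extra[take, , drop = FALSE]))
  kinetic_scheme(n, ft, activity_edges = paste0("k", n - 1L, 0L))
}

#' Draw log-uniform random rates for a scheme
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param log10_range range of log10 rates to draw uniformly from.
#' @return a named rate vector covering every edge.
#' @export
random_rates <- function(scheme, log10_range = c(-3, 3)) {
  sym <- scheme$edges$symbol
  r <- 10^stats::runif(length(sym), log10_range[1], log10_range[2])
  names(r) <- sym
  r
}
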