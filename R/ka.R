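#' Enumerate the King-Altman diagrams of a scheme
#'
#' A King-Altman diagram is an acyclic directed subgraph with exactly
#' \eqn{n-1} edges in which every non-terminal state has one outgoing edge
#' and all paths lead to a single terminal state (a directed spanning
#' in-tree). The steady-state occupancy of each state is proportional to
#' the total weight of the diagrams terminating there, each weight being
#' the product of the diagram's rate constants. Irreversible steps are
#' simply absent directed edges, so no diagram ever uses them.
#'
#' Enumeration walks the product of per-state outgoing-edge choices for
#' each candidate terminal and keeps the choice functions whose successor
#' chains all reach the terminal (no cycles). This exhaustive strategy is
#' exact at the intended scheme sizes (3--6 states).
#'
#' @param scheme a strongly connected \code{\link{kinetic_scheme}}.
#' @return an object of class \code{"ka_diagram_set"}: list with
#'   \code{diagrams} (list of integer edge-index vectors into the scheme's
#'   edge table), \code{terminal} (0-based terminal state per diagram),
#'   \code{binary_matrix} (diagrams x edges 0/1 matrix \eqn{B}),
#'   \code{edge_symbols} (column order of \eqn{B}), and \code{n_states}.
#' @export
enumerate_ka_diagrams <- function(scheme) {
  sc <- is_strongly_connected(scheme)
  if (!sc)
    stop("scheme is not strongly connected; unreachable state(s): ",
         paste(attr(sc, "unreachable"), collapse = ", "))
  n <- scheme$n_states
  edges <- scheme$edges
  out_idx <- lapply(seq_len(n) - 1L, function(s) which(edges$from == s))
  diagrams <- list(); terminal <- integer()
  for (term in seq_len(n) - 1L) {
    nonterm <- setdiff(seq_len(n) - 1L, term)
    choice_sets <- out_idx[nonterm + 1L]
    if (any(vapply(choice_sets, length, 1L) == 0L)) next
    grid <- do.call(expand.grid, c(choice_sets, KEEP.OUT.ATTRS = FALSE))
    for (g in seq_len(nrow(grid))) {
      sel <- as.integer(grid[g, ])
      succ <- rep.int(NA_integer_, n)
      succ[nonterm + 1L] <- edges$to[sel]
      ok <- TRUE
      for (s in nonterm) {          # follow each chain; must hit terminal
        v <- s; steps <- 0L
        while (v != term) {
          v <- succ[v + 1L]; steps <- steps + 1L
          if (steps > n) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        diagrams[[length(diagrams) + 1L]] <- sort(sel)
        terminal <- c(terminal, term)
      }
    }
  }
  if (!length(diagrams)) stop("scheme admits no King-Altman diagrams")
  B <- matrix(0L, nrow = length(diagrams), ncol = nrow(edges),
              dimnames = list(NULL, edges$symbol))
  for (i in seq_along(diagrams)) B[i, diagrams[[i]]] <- 1L
  structure(list(diagrams = diagrams, terminal = terminal,
                 binary_matrix = B, edge_symbols = edges$symbol,
                 n_states = n),
            class = "ka_diagram_set")
}

#' @export
print.ka_diagram_set <- function(x, ...) {
  cat("King-Altman diagram set:", length(x$diagrams), "diagrams over",
      x$n_states, "states\n")
  cat("  per terminal state:",
      paste(tabulate(x$terminal + 1L, x$n_states), collapse = " "), "\n")
  invisible(x)
}

#' King-Altman steady state
#'
#' Computes the normalized steady-state occupancy
#' \eqn{(s_\infty)_\alpha = \sum_{\ell \to \alpha} \kappa_\ell /
#' \sum_{\ell'} \kappa_{\ell'}} where \eqn{\kappa_\ell} is the product of
#' rate constants over diagram \eqn{\ell}. Weights are accumulated in log
#' space with max-subtraction so that rate ratios spanning many decades do
#' not overflow.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param rates named rate vector.
#' @param diagrams a \code{\link{enumerate_ka_diagrams}} result for the same
#'   scheme (enumerated on demand if omitted).
#' @return occupancy vector summing to 1.
#' @export
steady_state_ka <- function(scheme, rates, diagrams = NULL) {
  if (is.null(diagrams)) diagrams <- enumerate_ka_diagrams(scheme)
  if (diagrams$n_states != scheme$n_states ||
      !identical(diagrams$edge_symbols, scheme$edges$symbol))
    stop("diagram set does not match the scheme")
  r <- effective_rates(scheme, rates)
  logw <- as.numeric(diagrams$binary_matrix %*% log(r))
  m <- max(logw)
  if (!is.finite(m)) stop("degenerate scheme: zero total diagram weight")
  w <- exp(logw - m)
  tot <- sum(w)
  s <- vapply(seq_len(scheme$n_states) - 1L,
              function(a) sum(w[diagrams$terminal == a]), 0) / tot
  names(s) <- paste0("s", seq_len(scheme$n_states) - 1L)
  s
}
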