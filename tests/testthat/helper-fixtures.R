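# Shared fixtures and independent oracles, built in code at test time.

cas9_rates_unit <- function() {
  r <- rep(1, 7)
  names(r) <- cas9_scheme()$edges$symbol
  r
}

# independent brute-force King-Altman enumeration: all (n-1)-subsets of the
# directed edges, kept when they form a spanning in-tree (undirected-acyclic,
# one out-edge per non-terminal, all paths reaching the terminal)
brute_force_diagrams <- function(scheme) {
  n <- scheme$n_states
  E <- nrow(scheme$edges)
  out <- list()
  for (sub in utils::combn(E, n - 1L, simplify = FALSE)) {
    from <- scheme$edges$from[sub]; to <- scheme$edges$to[sub]
    if (anyDuplicated(from)) next                 # one out-edge per state
    terminal <- setdiff(0:(n - 1L), from)
    if (length(terminal) != 1L) next
    succ <- rep(NA_integer_, n)
    succ[from + 1L] <- to
    ok <- TRUE
    for (s in from) {
      v <- s; steps <- 0L
      while (v != terminal) {
        v <- succ[v + 1L]; steps <- steps + 1L
        if (is.na(v) || steps > n) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- list(edges = sort(sub),
                                            terminal = terminal)
  }
  out
}

# normalized kernel of the conservative rate matrix (dense null-space solve)
null_space_steady_state <- function(scheme, rates) {
  K <- build_rate_matrix(scheme, rates, conservative = TRUE)
  v <- svd(K)$v[, scheme$n_states]
  v <- v / sum(v)
  if (any(v < -1e-9)) v <- -v
  abs(v) / sum(abs(v))
}

# small in vitro fixture shared by model tests
invitro_fixture <- function(n = 400L, seed = 42L) {
  cfg <- sim_config(seed = 3L)
  d <- simulate_invitro(cfg, n, seed = seed)
  X <- kinn:::pairing_array(d, cfg$L)
  arch <- kinn_architecture(
    cfg$scheme,
    data.frame(symbol = cfg$windows$symbol, start = cfg$windows$start,
               end = cfg$windows$end, kernel = 1L),
    input_length = cfg$L, channels = 4L)
  list(cfg = cfg, data = d, X = X, arch = arch)
}

random_alignment <- function(with_indel = FALSE) {
  guide <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  pam <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
               collapse = "")
  ref <- strsplit(paste0(pam, guide), "")[[1]]
  al <- ref
  for (p in which(runif(23) < 0.1))
    al[p] <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1)
  if (with_indel) {
    pos <- sample(4:23, 1)
    if (runif(1) < 0.5) al <- append(al, tolower(sample(c("A", "C", "G", "T"), 1)),
                                     after = pos)
    else al[pos] <- "-"
  }
  list(guide = guide, pam = pam, target = paste(al, collapse = ""))
}
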