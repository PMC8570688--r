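#' Build random directed connectivity
#'
#' Erdos-Renyi directed graph over the `n_exc + n_inh` neurons: every ordered
#' pair of distinct cells is connected independently with probability `p`
#' (default 0.2).  Self-connections are excluded.  Stored sparsely in
#' compressed form (per-presynaptic-neuron target lists).
#'
#' @param n_exc,n_inh population sizes; excitatory neurons occupy indices
#'   `1..n_exc`, inhibitory neurons `n_exc+1..n_exc+n_inh`.
#' @param p connection probability in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return object of class `connectivity`: list with `targets` (0-based
#'   concatenated target indices), `offsets` (0-based CSR offsets, length
#'   N+1), `n_exc`, `n_inh`, `p`, `seed`.
#' @export
#' @examples
#' cm <- build_connectivity(40, 10, 0.2, seed = 1)
#' mean(diff(cm$offsets))  # ~ 0.2 * 49
build_connectivity <- function(n_exc, n_inh, p = 0.2, seed = 1L) {
  if (!is.numeric(n_exc) || !is.numeric(n_inh) || n_exc < 0 || n_inh < 0)
    stop("invalid configuration: population counts must be non-negative",
         call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("invalid configuration: p must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n_exc + n_inh)
  if (n == 0) stop("invalid configuration: empty network", call. = FALSE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  targets <- vector("list", n)
  if (p > 0) {
    for (j in seq_len(n)) {
      # directed edges j -> k, no self-connections
      deg <- rbinom(1L, n - 1L, p)
      if (deg > 0) {
        tk <- sample.int(n - 1L, deg)
        tk[tk >= j] <- tk[tk >= j] + 1L
        targets[[j]] <- sort(tk) - 1L
      } else targets[[j]] <- integer(0)
    }
  } else {
    for (j in seq_len(n)) targets[[j]] <- integer(0)
  }
  lens <- vapply(targets, length, 1L)
  structure(list(targets = unlist(targets, use.names = FALSE),
                 offsets = c(0L, cumsum(lens)),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 p = p, seed = as.integer(seed)),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("connectivity: %d neurons (%d exc, %d inh), p = %g, %d edges\n",
              x$n_exc + x$n_inh, x$n_exc, x$n_inh, x$p, length(x$targets)))
  invisible(x)
}

# preserve caller's RNG state around internally seeded draws
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
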