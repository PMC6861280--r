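#' Run code with a private random stream
#'
#' Seeds the RNG, runs `expr`, and restores the caller's `.Random.seed`, so
#' simulations never disturb (nor depend on) global RNG state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# connected components over n nodes given an m x 2 matrix of undirected edges;
# returns the component representative of each node (union-find, path halving)
uf_components <- function(n, pairs) {
  parents <- seq_len(n)
  find <- function(i) {
    while (parents[i] != i) {
      parents[i] <<- parents[parents[i]]
      i <- parents[i]
    }
    i
  }
  if (!is.null(pairs) && length(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parents[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
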