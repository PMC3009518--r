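#' Derive a reproducible child seed from a root seed and a label
#'
#' All stochastic steps in the package (structure sampling, gene dropping,
#' phenotype assignment, configuration picking, permutation, replicates) draw
#' their seeds through this function so that a single root seed determines an
#' entire experiment while the substreams stay decoupled.
#'
#' @param root integer root seed.
#' @param ... labels (character or integer) naming the substream.
#' @return An integer in \code{[0, 2^31 - 2]} suitable for \code{set.seed}.
#' @export
derive_seed <- function(root, ...) {
  labs <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(root) %% 2147483647
  for (lab in labs) {
    for (cp in utf8ToInt(lab)) h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# run `expr` under a temporary RNG state seeded with `seed`; if seed is NULL
# the expression uses (and advances) the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
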