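#' Derive an independent sub-seed from a master seed
#'
#' A single run seed feeds several independent random streams (subject
#' generation, fold splitting, weight initialisation, minibatch shuffling).
#' Sub-seeds are derived with a small integer hash of the master seed and a
#' stream tag so the streams stay decoupled but fully reproducible.
#'
#' @param seed master integer seed.
#' @param ... stream tags (integers or strings).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (tag in list(...)) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_len(nchar(tag)))
    # multiply-add hash mod the Mersenne prime 2^31 - 1, kept in double
    # precision range (operands < 2^31, products < 2^53)
    h <- ((h + as.numeric(tag) + 1) * 48271) %% 2147483647
    h <- (h * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
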