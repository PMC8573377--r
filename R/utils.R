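#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed` and
#' restores the previous RNG state afterwards, so seeded operations never
#' leak into (or depend on) surrounding random state. With `seed = NULL`
#' the expression runs on the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        suppressWarnings(rm(".Random.seed", envir = globalenv())),
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

# derive a stream of child seeds from one parent seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal cache (sense codon table etc.)
.bilatrep_cache <- new.env(parent = emptyenv())
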