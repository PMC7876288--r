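#' Derive a child seed from a root seed
#'
#' Every stochastic operation in the pipeline takes an explicit seed. Stages
#' derive their own seeds from a single root seed so that one integer fixes
#' the whole run while stages stay independently reproducible.
#'
#' @param root integer root seed.
#' @param label character label of the consuming operation.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(label))
  # small string hash (djb2), folded with the root seed into 31 bits
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(root) * 2654435761) %% 2147483647)
}

#' Run code under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# A value-with-reason sentinel: features that cannot be computed are NA with
# a machine-readable reason code instead of poisoning downstream stages.
undefined_value <- function(reason) {
  structure(NA_real_, reason = reason)
}

reason_of <- function(x) attr(x, "reason", exact = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
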