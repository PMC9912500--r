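#' Derive replicate seeds from a master seed
#'
#' Deterministic derivation used everywhere the package needs several
#' independent RNG streams from one master integer: seed `k` is the `k`-th
#' draw of `sample.int(2^31 - 2)` under `set.seed(master)`. The caller's RNG
#' state is left untouched.
#'
#' @param master Integer master seed.
#' @param k Number of seeds to derive.
#' @return Integer vector of length `k`.
#' @export
derive_seeds <- function(master, k) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(2147483646L, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
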