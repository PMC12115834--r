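#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Generators that draw several independent streams from one user seed fan the
#' seed out deterministically: substream `i` uses `(seed + 7919 * i) mod
#' (2^31 - 1)`. The multiplier is an arbitrary prime; the point is only that
#' distinct indices give distinct, reproducible seeds.
#'
#' @param seed integer master seed.
#' @param index non-negative integer substream index.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

stop_domain <- function(msg, class) {
  stop(structure(
    class = c(class, "loomstrike_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
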