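#' @keywords internal
"_PACKAGE"

# Fail with a classed condition so callers/tests can distinguish error kinds.
stop_nirshift <- function(msg, class) {
  stop(structure(
    class = c(class, "nirshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a per-component seed from a global seed
#'
#' A single run seed fans out to per-component seeds through a fixed integer
#' hash of a short component tag, so that e.g. the simulator and the training
#' loop never share an RNG stream. The derivation is deterministic and keeps
#' results inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer global seed.
#' @param tag short character tag naming the consumer (e.g. `"train"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

# Repeat a bias row-wise onto an n-row matrix without forming big intermediates.
.add_bias <- function(Z, b) sweep(Z, 2L, b, "+")

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
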