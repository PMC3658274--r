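#' @keywords internal
"_PACKAGE"

## Deterministic per-stage sub-seeds derived from one user-facing seed.
## All randomness in the package flows through this so that a single integer
## reproduces a full run; results stay below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(stage))
  h <- sum(chars * seq_along(chars)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## choose(n, 2) without overflow surprises for small n
n_pairs <- function(n) as.numeric(n) * (n - 1) / 2
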