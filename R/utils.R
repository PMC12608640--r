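# Internal utilities: scoped RNG and stable per-stream sub-seeds.

# Run `expr` under a given seed without disturbing the caller's RNG state.
# seed = NULL uses the current stream (and does advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from a base seed and a string tag, so each
# feature draws from its own stream: adding or reordering features never
# perturbs the values of the others. Polynomial string hash carried out in
# doubles (exact: intermediates stay far below 2^53).
sub_seed <- function(seed, tag) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(as.character(tag))))
    h <- (h * 131 + b) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
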