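# Internal helpers: local seeding and seed derivation.

# Evaluate expr with the given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a per-replicate RNG seed
#'
#' Mixes a global seed with a replicate index into an independent child seed
#' so replicates are reproducible regardless of execution order (one RNG
#' stream per replicate). Uses a Weyl/LCG-style integer mix; results stay
#' below 2^31.
#'
#' @param globalSeed single integer seed.
#' @param index replicate index (vectorized).
#' @return integer seed(s) in `[0, 2^31)`.
#' @examples
#' deriveSeed(1, 1:3)
#' @export
deriveSeed <- function(globalSeed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(globalSeed) %% m) * 48271 %% m
  v <- (s + as.numeric(index) * 69621 + 12345) %% m
  # one more multiplicative scramble to decorrelate adjacent indices
  as.integer((v * 16807) %% m)
}

# 32-bit polynomial rolling hash of a character vector; used for config
# manifests (content fingerprint, not cryptographic).
contentHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
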