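# Evaluate `expr` under a temporary RNG state so library calls never
# perturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# n independent run seeds derived deterministically from one master seed;
# all stay well below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Polynomial rolling hash over bytes, accumulated modulo a Mersenne
# prime so every intermediate stays exactly representable as a double.
hash_bytes <- function(bytes) {
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

hash_string <- function(s) hash_bytes(utf8ToInt(s))

# Checksum of a split's windowed samples; used to assert that every
# method in a comparison saw byte-identical train/test data.
split_checksum <- function(split) {
  x <- c(split$train$inputs, split$train$target, split$train$anchor_day,
         split$test$inputs, split$test$target, split$test$anchor_day)
  h <- hash_bytes(utf8ToInt(paste(sprintf("%.17g", as.numeric(x)),
                                  collapse = ",")))
  sprintf("%08x", h)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)
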