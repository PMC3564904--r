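# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69069 + k * 1234567) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
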