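## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Deterministic sub-seed derivation: a Lehmer-style hash keeping results in
## [1, 2^31 - 2] so they are always valid 32-bit R seeds.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m)
  for (ki in c(k, 1L)) {
    s <- (s * 48271 + abs(ki) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

## Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_named <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "evoselect_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## Compact mask key for fitness caching.
mask_key <- function(mask) paste(as.integer(mask), collapse = "")
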