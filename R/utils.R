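## Internal helpers: seed derivation, hashing, argument checks.

# Deterministic 31-bit mix; multiplier kept small so every intermediate
# product stays below 2^53 and the arithmetic is exact in doubles.
mix31 <- function(x) {
  x <- (x * 69069 + 1234567) %% 2147483647
  x <- (x * 40692 + 7654321) %% 2147483647
  x
}

#' Derive a reproducible stage/sample seed from a master seed
#'
#' Counter-based scheme: the derived seed depends only on the master seed, a
#' stage label and an index, so adding stages or methods to a pipeline never
#' perturbs the random draws of another stage.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index integer counter (e.g. sample index), default 0.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage = "stage", index = 0) {
  h <- mix31(as.numeric(master) %% 2147483647)
  for (code in utf8ToInt(as.character(stage))) h <- mix31(h + code)
  h <- mix31(h + as.numeric(index))
  as.integer(h %% 2147483645 + 1)
}

# FNV-1a over serialized R objects; used to stamp outputs with a config hash.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

git_describe_string <- function() {
  out <- tryCatch(
    suppressWarnings(system2("git", c("describe", "--always", "--dirty"),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  if (length(out) == 0 || is.null(out)) "unknown" else out[[1]]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  invisible(x)
}

frobenius <- function(m) sqrt(sum(m^2))

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
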