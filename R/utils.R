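#' @keywords internal
#' @useDynLib ledmesh, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out to named per-stage seeds so pipeline stages can be
#' re-run independently yet reproducibly. The derived seed is always a
#' non-negative integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. "synth", "train", "eval").
#' @return An integer seed.
#' @export
fanout_seed <- function(seed, stage) {
  h <- string_hash(paste0(stage, ":", as.integer(seed)))
  as.integer(h[1] %% 2147483647)
}

# Two polynomial rolling hashes (moduli < 2^26 keep all double arithmetic
# exact); returned as a length-2 numeric. Used only for fingerprinting.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  m1 <- 67108859; m2 <- 67108837
  h1 <- 17; h2 <- 29
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% m1
    h2 <- (h2 * 37 + b) %% m2
  }
  c(h1, h2)
}

# Stable hex digest of numeric/integer content, used to fingerprint
# topologies and bases so that training refuses mismatched artifacts.
content_hash <- function(...) {
  parts <- list(...)
  s <- paste(
    vapply(parts, function(p) paste(format(p, digits = 10), collapse = ","),
           character(1)),
    collapse = "|"
  )
  paste(sprintf("%08.0f", string_hash(s)), collapse = "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
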