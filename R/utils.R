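# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# deterministic substream seed derived from a global seed; kept < 2^31 - 1
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 104729) %% 2147483587) + 1L
}

# run expr under a local RNG state seeded with `seed`
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

# FNV-1a 32-bit hash of a character scalar; used for provenance manifests.
# All arithmetic stays below 2^53 so doubles carry it exactly.
fnv1a_hash <- function(x) {
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
      bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  }
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# stable text rendering of a (possibly nested) config list for hashing
deparse_config <- function(x) {
  paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
        collapse = "")
}

# round half-up to `digits` decimals (R's round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
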