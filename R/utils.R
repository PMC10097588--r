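# Internal helpers: classed conditions, seeded streams, unit conversion.

cs_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("cellspring_error_", class), "cellspring_error"), ...)
}

cs_warn <- function(message, class, ...) {
  rlang::warn(message, class = c(paste0("cellspring_warning_", class), "cellspring_warning"), ...)
}

#' Derive a reproducible child seed from a master seed and an identifier
#'
#' Every stochastic generator in the package draws from its own stream, keyed
#' by a master seed plus a stable string identifier (treatment label, curve
#' id, replicate index). The derivation is a 32-bit FNV-1a hash folded into
#' the positive integer range, so streams are independent of the order in
#' which datasets or curves are generated.
#'
#' @param master_seed Integer master seed.
#' @param id Character identifier of the stream.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "GM")
#' derive_seed(1, "PS")
derive_seed <- function(master_seed, id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  h <- fnv1a32(paste0(format(master_seed, scientific = FALSE), "/", id))
  as.integer(h %% 2147483629L) + 1L
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic
# (exact: intermediate products stay below 2^53).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# bitwXor for doubles holding 32-bit unsigned values
bitwXor2 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# Evaluate fn() with a local RNG state seeded by `seed`.
with_stream <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# SI conversion factors for the units accepted in curve file headers.
.length_units <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9)
.force_units  <- c(N = 1, mN = 1e-3, uN = 1e-6, "µN" = 1e-6, nN = 1e-9, pN = 1e-12)

si_factor <- function(unit, table, what) {
  f <- unname(table[unit])
  if (is.na(f)) {
    cs_abort(sprintf("unknown %s unit '%s'", what, unit), "invalid_unit")
  }
  f
}

# FNV-1a hash of a canonical JSON serialisation, as an 8-hex-digit string.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  h <- fnv1a32(as.character(js)) # may exceed the integer range; format in halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
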