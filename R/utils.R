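# Shared small helpers: rounding, timestamp parsing, seed derivation.

#' Round half away from zero
#'
#' Report tables round halves up (5.5 -> 6), unlike [base::round()]'s
#' round-half-even. Internal values are kept at full precision; this is
#' applied only when printing summary tables.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse timestamps given as ISO-8601 ("YYYY-MM-DD HH:MM:SS", "T" separator
# allowed) or "DD/MM/YYYY HH:MM:SS". All times are treated as UTC; no DST
# logic anywhere in the package. Unparsable entries come back NA.
parse_timestamp <- function(x) {
  x <- trimws(gsub("T", " ", as.character(x), fixed = TRUE))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  slash <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}", x)
  if (any(slash)) {
    out[slash] <- as.POSIXct(x[slash], format = "%d/%m/%Y %H:%M:%S", tz = "UTC")
    # date-only variant
    bad <- slash & is.na(out)
    out[bad] <- as.POSIXct(x[bad], format = "%d/%m/%Y", tz = "UTC")
  }
  iso <- !slash
  if (any(iso)) {
    out[iso] <- as.POSIXct(x[iso], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    bad <- iso & is.na(out)
    out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d", tz = "UTC")
  }
  out
}

# Deterministic 31-bit sub-seed from a base seed and stream labels, so every
# randomized stage (fold, boosting step, bootstrap replicate) is reproducible
# from one user seed without ever exceeding .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 31 + (as.numeric(p) %% 1000003)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
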