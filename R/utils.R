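# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a root seed and a stage key.
# Kept well below .Machine$integer.max.
.subSeed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 101L) %% 2147483647L
}

# Quantile convention used throughout the package: type 6 (linear
# interpolation of order statistics, the convention of SPSS), so medians and
# IQRs match the reporting style of clinical statistics software.
.q6 <- function(x, p) {
  as.numeric(stats::quantile(x, probs = p, type = 6, names = FALSE,
                             na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an arbitrary R object via its canonical JSON serialization.
.objectHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
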