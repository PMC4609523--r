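#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed and counters.
# Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(master, ...) {
  ctr <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in ctr) s <- (s * 7919 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

assert_binary <- function(x, what = "labels") {
  if (anyNA(x)) stop(what, " contain missing values", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop(what, " must be binary (0/1)", call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
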