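# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Set the RNG state when a seed is supplied; no-op otherwise. Generators call
# this once at entry so a fixed seed gives bit-identical output.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stopf("seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# strict finite numeric vector check
check_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stopf("%s must be finite numeric with no missing values", name)
  if (positive && any(x <= 0)) stopf("%s must be strictly positive", name)
  invisible(x)
}

dna_complement <- function(alleles) {
  map <- c(A = "T", T = "A", C = "G", G = "C")
  out <- map[toupper(alleles)]
  unname(out)
}

is_palindromic <- function(a1, a2) {
  dna_complement(a1) == toupper(a2)
}
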