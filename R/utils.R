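# Shared internal helpers: sequence coercion and small validators.

# Coerce a sequence input (character scalar, DNAString, or length-1
# DNAStringSet) to an uppercase plain character string.
.as_dna_string <- function(x, arg = "seq") {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1L) {
      stop(sprintf("'%s' must contain exactly one sequence", arg), call. = FALSE)
    }
    x <- x[[1L]]
  }
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single DNA sequence", arg), call. = FALSE)
  }
  toupper(x)
}

.dna_chars <- function(x) strsplit(.as_dna_string(x), "", fixed = TRUE)[[1L]]

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.as_dna_string(x))))
}

.check_acgt <- function(x, arg = "seq") {
  if (grepl("[^ACGT]", x)) {
    stop(sprintf("'%s' contains characters other than A/C/G/T", arg), call. = FALSE)
  }
  invisible(x)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.gc_fraction <- function(seq) {
  ch <- .dna_chars(seq)
  sum(ch %in% c("G", "C")) / length(ch)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a reproducible child seed (kept within 32-bit integer range).
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1664525) %% 2147483647)
}
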