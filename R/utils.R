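DNA_BASES <- c("A", "C", "G", "T")

# Random DNA string of length n (uses the current RNG state).
rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# A different base than `base`, uniformly at random (vectorised).
other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L),
         character(1), USE.NAMES = FALSE)
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# Mutate each base: transition partner with probability ts_prob, else one
# of its two transversion partners uniformly.
mutate_base <- function(base, ts_prob) {
  vapply(base, function(b) {
    if (runif(1) < ts_prob) {
      TRANSITION_PARTNER[[b]]
    } else {
      sample(setdiff(DNA_BASES, c(b, TRANSITION_PARTNER[[b]])), 1L)
    }
  }, character(1), USE.NAMES = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

stop_arg <- function(...) abort(paste0(...), class = "qtlsnp_argument_error")

check_base <- function(x, arg) {
  if (!(is.character(x) && length(x) == 1L && x %in% DNA_BASES)) {
    stop_arg("`", arg, "` must be a single base in A/C/G/T, got: ",
             paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Translate a codon (character of length 3) with the standard genetic code.
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop_arg("not a valid codon: ", codon)
  aa
}
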