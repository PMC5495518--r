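# shared internal helpers

# reverse complement for plain character vectors (ACGTN only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# check a length-1 positive integer-ish value
assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  as.numeric(x)
}

# flip strand label(s)
other_strand <- function(s) ifelse(s == "+", "-", "+")
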