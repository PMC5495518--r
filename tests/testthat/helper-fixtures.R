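# Shared fixtures built in code: small gene models, random toy loci and
# brute-force oracles used across the test files.

toy_gene <- function(strand = "+") {
  gene_model("toy", "chrT", strand,
             data.frame(start = c(100, 300, 500), end = c(200, 400, 650)))
}

# random gene model + reference on a small locus, for property tests
random_locus <- function(n_exons = sample(1:4, 1), strand = sample(c("+", "-"), 1)) {
  exon_len <- sample(30:120, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(20:60, n_exons - 1, replace = TRUE) else integer()
  starts <- 50 + c(0, cumsum(head(exon_len, -1) + intron_len))
  g <- gene_model("rand", "chrR", strand,
                  data.frame(start = starts, end = starts + exon_len))
  ref_len <- g$transcript_end + 50
  reference <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                     collapse = "")
  list(gene = g, reference = reference)
}

# random aligned-read set over a window
random_alignments <- function(n, lo, hi, len_range = c(18, 24)) {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample(seq(lo - 30, hi + 10), n, replace = TRUE)
  tibble::tibble(
    read_id = sprintf("r%d", seq_len(n)),
    start = start, length = len,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# brute-force per-base overlap coverage oracle
oracle_coverage <- function(aln, lo, hi) {
  v <- numeric(hi - lo)
  for (i in seq_len(nrow(aln))) {
    s <- max(aln$start[i], lo); e <- min(aln$start[i] + aln$length[i], hi)
    if (e > s) v[(s - lo + 1):(e - lo)] <- v[(s - lo + 1):(e - lo)] + 1
  }
  v
}

# naive full-scan exact-match mapping oracle (both strands)
oracle_map <- function(seq, reference) {
  hits <- list()
  w <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  for (s in 0:(nchar(reference) - w)) {
    sub <- substr(reference, s + 1, s + w)
    if (sub == seq) hits[[length(hits) + 1]] <- list(start = s, strand = "+")
    if (sub == rc) hits[[length(hits) + 1]] <- list(start = s, strand = "-")
  }
  hits
}

# independent per-point tricube weighted-least-squares LOESS oracle
oracle_loess <- function(x, y, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d)[q]
    w <- (1 - pmin(d / dmax, 1)^3)^3
    use <- w > 0
    X <- outer(x[use] - x0, 0:degree, `^`)
    W <- diag(w[use])
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[use])
    beta[1, 1]
  }, numeric(1))
}
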