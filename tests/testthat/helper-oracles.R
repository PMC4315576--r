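# Independent oracles and small fixture builders used across the suite.

# Brute-force affine-gap local alignment score: a plain full-matrix DP,
# written independently of the package's alignment engine so the two can
# disagree.  Gap of length L costs gap_open + L * gap_extend.
sw_score_oracle <- function(q, t, match = 2, mismatch = 4,
                            gap_open = 6, gap_extend = 1) {
  qq <- strsplit(q, "")[[1]]
  tt <- strsplit(t, "")[[1]]
  m <- length(qq); n <- length(tt)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-1e9, m + 1, n + 1)
  F <- matrix(-1e9, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      s <- if (qq[i - 1] == tt[j - 1]) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# one mapped-read row for pileup/coverage fixtures
aln_row <- function(pos, cigar, seq, contig = "ref", mapq = 60L,
                    strand = "+", qual = NULL, qname = "r") {
  tibble::tibble(qname = qname, pair_id = 1L, mate = 1L, contig = contig,
                 pos = as.integer(pos), strand = strand, cigar = cigar,
                 mapq = as.integer(mapq), score = 0L, second_score = NA_integer_,
                 seq = seq, qual = qual %||% strrep("?", nchar(seq)),
                 proper_pair = TRUE, mapped = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a single-site pileup tibble with given depth and one alt allele count
pileup_site <- function(pos, ref, alt, alt_count, depth,
                        contig = "master") {
  counts <- as.integer(c(depth - alt_count, alt_count))
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref = ref,
    depth = as.integer(depth), n_lowbq = 0L, n_lowmq = 0L,
    allele = c(ref, alt), count = counts,
    is_ref = c(TRUE, FALSE))
}

# exhaustive set-comparison oracle for sensitivity/specificity
eval_oracle <- function(calls_key, truth_key, n_positions) {
  tp <- sum(truth_key %in% calls_key)
  fn <- length(truth_key) - tp
  fp <- sum(!calls_key %in% truth_key)
  list(tp = tp, fn = fn, fp = fp,
       sensitivity = if (length(truth_key)) tp / length(truth_key) else NA)
}
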