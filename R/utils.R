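# Shared helpers.  All genomic intervals in this package are tibbles with
# columns contig, start, end in 0-based half-open coordinates; 1-based
# formats (VCF, SAM) are converted at the file boundary only.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Interval tibble constructor
#'
#' @param contig Contig name (recycled).
#' @param start,end 0-based half-open bounds.
#' @param name Optional interval labels.
#' @return A tibble with columns `contig`, `start`, `end` (and `name`).
#' @export
intervals <- function(contig, start, end, name = NULL) {
  out <- tibble(contig = contig, start = as.integer(start), end = as.integer(end))
  if (!is.null(name)) out$name <- name
  stopifnot(all(out$end >= out$start))
  out
}

# membership of 0-based positions in an interval tibble (single contig or
# matching contig column supplied)
pos_in_intervals <- function(pos, ivs, contig = NULL) {
  if (is.null(ivs) || nrow(ivs) == 0) return(rep(FALSE, length(pos)))
  if (!is.null(contig)) ivs <- ivs[ivs$contig %in% contig, , drop = FALSE]
  if (nrow(ivs) == 0) return(rep(FALSE, length(pos)))
  ir <- IRanges::IRanges(start = ivs$start + 1L, end = ivs$end)
  IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), ir)
}

# all 0-based positions covered by an interval tibble
interval_positions <- function(ivs) {
  if (nrow(ivs) == 0) return(integer())
  sort(unique(unlist(Map(seq.int, ivs$start, ivs$end - 1L))))
}

dilate_intervals <- function(ivs, flank, contig_length = Inf) {
  ivs$start <- pmax(0L, ivs$start - as.integer(flank))
  ivs$end <- as.integer(pmin(contig_length, ivs$end + flank))
  ivs
}

# reference length consumed by a CIGAR string
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "" || cg == "*") return(0L)
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# draw a substitute base different from `ref` for each element
other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) {
    sample(setdiff(bases, b), 1L)
  }, character(1), USE.NAMES = FALSE)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
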