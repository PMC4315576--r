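#' Alignment scoring scheme
#'
#' Common short-read local-alignment defaults: match +2, mismatch 4, gap
#' open 6, gap extend 1 (a gap of length L costs `gap_open + L *
#' gap_extend`).
#'
#' @param match Match score (> 0).
#' @param mismatch,gap_open,gap_extend Penalties (>= 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 4L, gap_open = 6L,
                           gap_extend = 1L) {
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (min(mismatch, gap_open, gap_extend) < 0) {
    stop("penalties must be non-negative", call. = FALSE)
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties, with deterministic
#' tie-breaking (smaller target start, then shorter target span). The
#' operation string uses CIGAR conventions relative to the query: `M`
#' consumes both sequences, `I` the query only, `D` the target only, with
#' `S` marking unaligned query ends.
#'
#' @param query,target Nucleotide strings.
#' @param scheme A [scoring_scheme()].
#' @param max_hits Maximum number of co-optimal placements to return.
#' @return A tibble with one row per placement: `score`, `query_start`,
#'   `query_end`, `target_start`, `target_end` (0-based half-open), `cigar`.
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme(),
                           max_hits = 1L) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("query and target must be non-empty", call. = FALSE)
  }
  res <- cpp_smith_waterman(query, target, scheme$match, scheme$mismatch,
                            scheme$gap_open, scheme$gap_extend,
                            as.integer(max_hits))
  as_tibble(res)
}

#' Build a k-mer seed index over reference contigs
#'
#' Exact k-mer index retaining multi-mapping k-mers, used by the built-in
#' seed-and-extend mapper. The index is an in-memory handle valid for the
#' current session.
#'
#' @param reference Named character vector of contig sequences, or a
#'   `locus_model` (indexed via [locus_reference()]).
#' @param k K-mer length (>= 11).
#' @return A `kmer_index` handle.
#' @export
build_kmer_index <- function(reference, k = 21L) {
  if (inherits(reference, "locus_model")) reference <- locus_reference(reference)
  if (k < 11) stop("k must be >= 11", call. = FALSE)
  if (k > min(nchar(reference))) {
    stop("k larger than the shortest contig", call. = FALSE)
  }
  if (is.null(names(reference))) {
    names(reference) <- paste0("contig", seq_along(reference))
  }
  idx <- cpp_build_index(reference, as.integer(k))
  attr(idx, "reference") <- reference
  idx
}

#' Look up a k-mer in a seed index
#'
#' @param index A [build_kmer_index()] handle.
#' @param kmer K-mer string of the index's k; anything else (including
#'   k-mers containing N) returns an empty result.
#' @return Tibble of `contig`, `pos` (0-based) hits; zero rows if absent.
#' @export
kmer_lookup <- function(index, kmer) {
  as_tibble(cpp_kmer_lookup(index, kmer))
}

#' Map simulated read pairs with the built-in mapper
#'
#' Seed-and-extend mapping against the combined master/pseudogene
#' reference: seed k-mers propose candidate loci, candidates are scored
#' gaplessly and re-scored by Smith-Waterman when mismatches accumulate
#' (so indel-carrying and junction-spanning reads receive gapped or
#' soft-clipped alignments), and mates are placed jointly, maximising the
#' summed score under orientation and insert-size constraints. A mate with
#' an ambiguous placement is thereby resolved towards its anchor. Mapping
#' quality is `min(cap, 6 * (best - second best))` and 0 on ties; tied
#' best placements are assigned uniformly at random (reproducible under
#' `seed`), which is what lets pseudogene-identical reads drift between
#' master and copies as they do under production aligners.
#'
#' The built-in mapper exists so that competitive mapping is reproducible
#' at desk scale without external tools; production-size data would be
#' mapped externally and ingested with [load_alignments()]. No claim of
#' equivalence with any production aligner is made.
#'
#' @param pairs Read-pair tibble from [simulate_read_pairs()].
#' @param index A [build_kmer_index()] handle over the combined reference.
#' @param scheme A [scoring_scheme()].
#' @param outer_distance Expected outer distance (insert length).
#' @param outer_slack Allowed deviation from `outer_distance`.
#' @param max_mm_gapless Mismatch budget before a candidate is re-scored by
#'   Smith-Waterman.
#' @param mapq_cap Mapping-quality cap.
#' @param seed Seed for tie assignment.
#' @return Tibble of mapped reads: `qname`, `pair_id`, `mate`, `contig`,
#'   `pos` (0-based), `strand`, `cigar`, `mapq`, `score`, `second_score`,
#'   `seq` (reference orientation), `qual`, `proper_pair`, `mapped`.
#' @export
map_read_pairs <- function(pairs, index, scheme = scoring_scheme(),
                           outer_distance = 200L, outer_slack = 150L,
                           max_mm_gapless = 8L, mapq_cap = 60L, seed = NULL) {
  ref <- attr(index, "reference")
  res <- with_seed_if(seed, {
    cpp_map_read_pairs(index, pairs$read1, pairs$read2,
                       scheme$match, scheme$mismatch, scheme$gap_open,
                       scheme$gap_extend, as.integer(outer_distance),
                       as.integer(outer_slack), as.integer(max_mm_gapless),
                       6L, as.integer(mapq_cap), 30L)
  })
  out <- as_tibble(res)
  out$contig <- names(ref)[out$contig_idx]
  out$contig_idx <- NULL
  out$mapped <- !is.na(out$pos)
  # carry origin-derived read names and qualities
  out$qname <- sprintf("%s:%d:%s:%s:%d",
                       pairs$contig[out$pair_id], pairs$frag_start[out$pair_id],
                       pairs$strand[out$pair_id], pairs$haplotype[out$pair_id],
                       pairs$pair_id[out$pair_id])
  qual_fwd <- ifelse(out$mate == 1, pairs$qual1[out$pair_id],
                     pairs$qual2[out$pair_id])
  neg <- which(out$strand == "-")
  if (length(neg)) {
    qual_fwd[neg] <- as.character(
      Biostrings::reverse(Biostrings::BStringSet(qual_fwd[neg])))
  }
  out$qual <- qual_fwd
  out[, c("qname", "pair_id", "mate", "contig", "pos", "strand", "cigar",
          "mapq", "score", "second_score", "seq", "qual", "proper_pair",
          "mapped")]
}

#' Ingest alignments from SAM/BAM
#'
#' Translates externally produced alignments into the internal mapped-read
#' tibble: 1-based SAM positions become 0-based starts, strand and mate
#' are decoded from flags, and soft-clip information is preserved in the
#' CIGAR. Requires the Rsamtools package.
#'
#' @param path SAM or BAM file. Plain-text SAM is converted on the fly.
#' @param region Optional interval tibble restricting the query (BAM must
#'   then be indexed).
#' @return Tibble with `qname`, `contig`, `pos`, `strand`, `cigar`,
#'   `mapq`, `seq`, `qual`, `mate`, `proper_pair`, `mapped`.
#' @export
load_alignments <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("load_alignments requires the Rsamtools package", call. = FALSE)
  }
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (!is_bam) {
    dest <- tempfile(fileext = "")
    path <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM: ", conditionMessage(e),
                               call. = FALSE))
  }
  param_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = param_what)
  } else {
    gr <- GenomicRanges::GRanges(region$contig,
                                 IRanges::IRanges(region$start + 1L, region$end))
    Rsamtools::ScanBamParam(what = param_what, which = gr)
  }
  b <- Rsamtools::scanBam(path, param = param)
  b <- do.call(Map, c(list(f = c), b))  # merge region chunks
  flag <- b$flag
  tibble(
    qname = b$qname,
    contig = as.character(b$rname),
    pos = b$pos - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    cigar = as.character(b$cigar),
    mapq = as.integer(b$mapq),
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    mate = ifelse(bitwAnd(flag, 128L) > 0, 2L, 1L),
    proper_pair = bitwAnd(flag, 2L) > 0,
    mapped = bitwAnd(flag, 4L) == 0
  )
}

#' Write mapped reads as SAM
#'
#' Minimal plain-text SAM emission (header plus one line per mapped read)
#' so the built-in mapper's output can be consumed by standard tools and
#' round-tripped through [load_alignments()].
#'
#' @param alignments Mapped-read tibble.
#' @param reference Named character vector of contig sequences (for header
#'   lengths), or a `kmer_index`/`locus_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, reference, path) {
  if (inherits(reference, "locus_model")) reference <- locus_reference(reference)
  if (inherits(reference, "kmer_index")) reference <- attr(reference, "reference")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  a <- alignments[alignments$mapped, , drop = FALSE]
  flag <- ifelse(a$mate == 1L, 64L, 128L) + 1L +
    ifelse(a$strand == "-", 16L, 0L) +
    ifelse(isTRUE_vec(a$proper_pair), 2L, 0L)
  qual <- if ("qual" %in% names(a)) a$qual else strrep("?", nchar(a$seq))
  rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  a$qname, flag, a$contig, a$pos + 1L, a$mapq, a$cigar,
                  a$seq, qual)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
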