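#' Read-simulation parameters
#'
#' Defaults follow common short-read validation settings for duplicated
#' loci: 2 x 150 bp paired-end reads, an outer distance of 200 bp between
#' the two ends (so the mates overlap by 100 bp), a per-base substitution
#' error rate of 0.001 and 1000-fold target coverage. Coverage is accounted
#' per 200 bp sequencing fragment; see [pairs_for_coverage()].
#'
#' @param read_length Read length in bases.
#' @param outer_distance Outer distance between the two ends (the fragment
#'   length).
#' @param outer_distance_sd Standard deviation of the outer distance
#'   (default 0: fixed-length fragments).
#' @param base_error_rate Per-base substitution error probability.
#'   Sequencing-indel errors are not modelled.
#' @param target_coverage Fold coverage to aim for.
#' @param seed Integer seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 150L, outer_distance = 200L,
                            outer_distance_sd = 0, base_error_rate = 0.001,
                            target_coverage = 1000, seed = 1L) {
  if (base_error_rate < 0 || base_error_rate >= 1) {
    stop("base_error_rate must be in [0, 1)", call. = FALSE)
  }
  if (read_length > outer_distance) {
    # mates overlap; fragment-footprint coverage accounting handles this
    # (see pairs_for_coverage), so it is allowed, not an error
  }
  structure(list(read_length = as.integer(read_length),
                 outer_distance = as.integer(outer_distance),
                 outer_distance_sd = outer_distance_sd,
                 base_error_rate = base_error_rate,
                 target_coverage = target_coverage,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Read pairs needed for a target coverage
#'
#' Fragment-based accounting: one pair covers one fragment of
#' `fragment_length` bases, so `ceiling(coverage * region_length /
#' fragment_length)` pairs are required. With overlapping 2 x 150 bp mates
#' at an outer distance of 200 this equals the coverage of fragment
#' footprints; counting the 300 sequenced bases per pair instead would give
#' 1.5x this depth (use `accounting = "sequenced-bases"` for that
#' convention).
#'
#' @param region_length Region length in bases.
#' @param coverage Fold coverage.
#' @param fragment_length Fragment (outer distance) length in bases.
#' @param read_length Read length; only used for `"sequenced-bases"`.
#' @param accounting `"fragment"` (default) or `"sequenced-bases"`.
#' @return Integer number of read pairs.
#' @export
pairs_for_coverage <- function(region_length, coverage, fragment_length,
                               read_length = 150L,
                               accounting = c("fragment", "sequenced-bases")) {
  accounting <- match.arg(accounting)
  if (region_length <= 0 || coverage < 0 || fragment_length <= 0) {
    stop("region_length and fragment_length must be positive", call. = FALSE)
  }
  denom <- switch(accounting, fragment = fragment_length,
                  `sequenced-bases` = 2 * read_length)
  as.integer(ceiling(coverage * region_length / denom))
}

#' Build the two master haplotypes carrying the truth variants
#'
#' Heterozygous variants are placed on exactly one haplotype (chosen
#' uniformly unless `het_haplotype = "first"`), homozygous variants on
#' both. Returns the haplotype sequences together with coordinate maps
#' carrying the cumulative indel offsets between haplotype and master
#' coordinates.
#'
#' @param master Master sequence (character scalar).
#' @param truth A `truth_set` tibble. A pre-existing `haplotype` column
#'   (1, 2, or 0 for both) overrides the assignment policy, which lets an
#'   experiment phase variant classes onto separate haplotypes.
#' @param het_haplotype `"random"` or `"first"`.
#' @param seed Seed for the het assignment.
#' @return List with `sequences` (length-2 character), `assignment` (truth
#'   with a `haplotype` column; 0 = both), and `maps` (per-haplotype tibble
#'   of `master_pos`, `hap_pos` anchor pairs).
#' @export
make_haplotypes <- function(master, truth, het_haplotype = c("random", "first"),
                            seed = 1L) {
  het_haplotype <- match.arg(het_haplotype)
  if (nrow(truth) > 0) {
    validate_truth_set(truth, list(master = master))
    truth <- truth[order(truth$pos), ]
    # planting conflict: reference footprints may not overlap
    fp_end <- truth$pos + nchar(truth$ref) - 1L
    if (any(truth$pos[-1] <= fp_end[-length(fp_end)])) {
      stop("overlapping truth variants cannot be planted", call. = FALSE)
    }
  }
  with_seed_if(seed, {
    hap_of <- if (nrow(truth) == 0) integer() else if
    ("haplotype" %in% names(truth)) {
      ifelse(truth$zygosity == "hom", 0L, as.integer(truth$haplotype))
    } else switch(
      het_haplotype,
      random = ifelse(truth$zygosity == "hom", 0L,
                      sample(1:2, nrow(truth), replace = TRUE)),
      first = ifelse(truth$zygosity == "hom", 0L, 1L)
    )
    seqs <- character(2)
    maps <- vector("list", 2)
    for (h in 1:2) {
      rows <- which(hap_of == 0L | hap_of == h)
      seqs[h] <- apply_variants(master, truth[rows, , drop = FALSE])
      maps[[h]] <- coordinate_map(truth[rows, , drop = FALSE])
    }
    truth$haplotype <- hap_of
    list(sequences = seqs, assignment = truth, maps = maps)
  })
}

# apply anchored variants (sorted, non-overlapping) to a sequence
apply_variants <- function(master, truth) {
  if (nrow(truth) == 0) return(master)
  out <- master
  for (i in rev(seq_len(nrow(truth)))) {
    p <- truth$pos[i]
    out <- paste0(substr(out, 1L, p),
                  truth$alt[i],
                  substr(out, p + nchar(truth$ref[i]) + 1L, nchar(out)))
  }
  out
}

# anchors mapping master -> haplotype coordinates after each indel
coordinate_map <- function(truth) {
  if (nrow(truth) == 0) return(tibble(master_pos = 0L, hap_pos = 0L))
  shift <- cumsum(nchar(truth$alt) - nchar(truth$ref))
  tibble(master_pos = c(0L, truth$pos + nchar(truth$ref)),
         hap_pos = c(0L, truth$pos + nchar(truth$ref) + shift))
}

#' Simulate paired-end reads from one contig
#'
#' Fragment start positions are uniform over the valid range; read 1 is the
#' first `read_length` bases of the fragment and read 2 the reverse
#' complement of its last `read_length` bases (mate labels are swapped for
#' half the fragments so both orientations occur in R1/R2, as in real
#' libraries). Substitution errors are i.i.d. at `base_error_rate`.
#' Qualities are constant Q30. The true origin is recorded for evaluation.
#'
#' @param contig_sequence Source sequence (for a variant carrier, pass the
#'   haplotype sequence, not the reference).
#' @param params A [read_sim_params()].
#' @param n_pairs Number of pairs; defaults to [pairs_for_coverage()] at
#'   `params$target_coverage`.
#' @param contig_name Origin label stored with each pair.
#' @param haplotype Origin haplotype label.
#' @param seed Seed.
#' @return A tibble with one row per pair: `pair_id`, `contig`,
#'   `frag_start`, `strand`, `haplotype`, `read1`, `read2`, `qual1`,
#'   `qual2`.
#' @export
simulate_read_pairs <- function(contig_sequence, params = read_sim_params(),
                                n_pairs = NULL, contig_name = "contig",
                                haplotype = NA_character_,
                                seed = params$seed) {
  L <- nchar(contig_sequence)
  rl <- params$read_length
  if (L < params$outer_distance) {
    stop("contig shorter than the outer distance; cannot place fragments",
         call. = FALSE)
  }
  if (is.null(n_pairs)) {
    n_pairs <- pairs_for_coverage(L, params$target_coverage,
                                  params$outer_distance)
  }
  if (n_pairs == 0) {
    return(tibble(pair_id = integer(), contig = character(),
                  frag_start = integer(), strand = character(),
                  haplotype = character(), read1 = character(),
                  read2 = character(), qual1 = character(),
                  qual2 = character()))
  }
  with_seed_if(seed, {
    outer <- if (params$outer_distance_sd > 0) {
      pmax(rl, as.integer(round(stats::rnorm(n_pairs, params$outer_distance,
                                             params$outer_distance_sd))))
    } else rep(params$outer_distance, n_pairs)
    outer <- pmin(outer, L)
    start <- as.integer(floor(runif(n_pairs) * (L - outer + 1)))
    fwd <- substring(contig_sequence, start + 1L, start + rl)
    rev <- revcomp_chr(substring(contig_sequence, start + outer - rl + 1L,
                                 start + outer))
    swap <- runif(n_pairs) < 0.5
    read1 <- ifelse(swap, rev, fwd)
    read2 <- ifelse(swap, fwd, rev)
    if (params$base_error_rate > 0) {
      read1 <- inject_errors(read1, params$base_error_rate)
      read2 <- inject_errors(read2, params$base_error_rate)
    }
    q <- strrep(rawToChar(as.raw(30L + 33L)), rl)
    tibble(pair_id = seq_len(n_pairs), contig = contig_name,
           frag_start = start, strand = ifelse(swap, "-", "+"),
           haplotype = haplotype, read1 = read1, read2 = read2,
           qual1 = q, qual2 = q)
  })
}

# i.i.d. substitution errors on a vector of equal-length reads
inject_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  n_err <- rbinom(length(reads), rl, rate)
  idx <- which(n_err > 0)
  if (length(idx) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    p <- sample.int(rl, n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[p] <- vapply(ch[p], function(b) sample(setdiff(bases, b), 1L),
                    character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate reads for a whole locus
#'
#' Master haplotypes carry the truth variants and are each simulated at
#' half the target coverage; pseudogene contigs are always simulated from
#' their unmodified (wild-type) sequence at the full per-contig coverage.
#'
#' @param locus A `locus_model`.
#' @param truth A `truth_set` (may be empty).
#' @param params A [read_sim_params()].
#' @param seed Seed.
#' @return A tibble of read pairs (see [simulate_read_pairs()]).
#' @export
simulate_locus_reads <- function(locus, truth, params = read_sim_params(),
                                 seed = params$seed) {
  haps <- make_haplotypes(locus$master, truth, seed = seed)
  half <- params$target_coverage / 2
  out <- vector("list", 2 + nrow(locus$pseudogenes))
  for (h in 1:2) {
    n <- pairs_for_coverage(nchar(haps$sequences[h]), half,
                            params$outer_distance)
    out[[h]] <- simulate_read_pairs(haps$sequences[h], params, n,
                                    contig_name = "master",
                                    haplotype = paste0("hap", h),
                                    seed = seed + h)
  }
  for (k in seq_len(nrow(locus$pseudogenes))) {
    sq <- locus$pseudogenes$sequence[k]
    n <- pairs_for_coverage(nchar(sq), params$target_coverage,
                            params$outer_distance)
    out[[2 + k]] <- simulate_read_pairs(sq, params, n,
                                        contig_name = locus$pseudogenes$name[k],
                                        haplotype = "wild-type",
                                        seed = seed + 2L + k)
  }
  pairs <- bind_rows(out)
  pairs$pair_id <- seq_len(nrow(pairs))
  attr(pairs, "haplotypes") <- haps
  pairs
}

#' Write simulated pairs as FASTQ
#'
#' Read names encode the true origin as `contig:start:strand:haplotype:id`.
#'
#' @param pairs Tibble from [simulate_read_pairs()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  nm <- sprintf("%s:%d:%s:%s:%d", pairs$contig, pairs$frag_start,
                pairs$strand, pairs$haplotype, pairs$pair_id)
  for (m in 1:2) {
    sq <- Biostrings::DNAStringSet(pairs[[paste0("read", m)]])
    names(sq) <- nm
    Biostrings::writeXStringSet(
      sq, if (m == 1) r1_path else r2_path, format = "fastq",
      qualities = Biostrings::BStringSet(pairs[[paste0("qual", m)]]))
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ written by [write_fastq_pairs()]
#' @param r1_path,r2_path FASTQ paths.
#' @return A read-pair tibble with origin fields decoded from names.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq", with.qualities = TRUE)
  f <- strsplit(names(s1), ":", fixed = TRUE)
  tibble(
    pair_id = vapply(f, function(x) as.integer(x[5]), integer(1)),
    contig = vapply(f, `[`, character(1), 1),
    frag_start = vapply(f, function(x) as.integer(x[2]), integer(1)),
    strand = vapply(f, `[`, character(1), 3),
    haplotype = vapply(f, `[`, character(1), 4),
    read1 = unname(as.character(s1)), read2 = unname(as.character(s2)),
    qual1 = unname(as.character(S4Vectors::mcols(s1)$qualities)),
    qual2 = unname(as.character(S4Vectors::mcols(s2)$qualities))
  )
}
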