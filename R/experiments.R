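# Desk-scale simulation experiments: CNV recovery against a control panel
# and split-read breakpoint recovery on planted deletions.  These drive the
# validation suite and the reproduction script; they only use the package's
# own public operations.

#' Simulate one sample for depth-based CNV analysis
#'
#' Simulates a diploid sample over a master-only locus and maps it with
#' the built-in mapper. A heterozygous genomic deletion covering
#' `deleted_exons` (including the flanking half-introns) can be planted on
#' one haplotype, halving the depth over those exons.
#'
#' @param locus A `locus_model` (pseudogenes not required).
#' @param deleted_exons Integer vector of exon indices deleted on one
#'   haplotype (must be consecutive), or empty for a normal sample.
#' @param coverage Total fold coverage (split over the two haplotypes).
#' @param index A [build_kmer_index()] over the master (built on the fly
#'   if `NULL`).
#' @param reads A [read_sim_params()].
#' @param seed Seed.
#' @return Mapped-read tibble for the sample.
#' @export
simulate_cnv_sample <- function(locus, deleted_exons = integer(0),
                                coverage = 200, index = NULL,
                                reads = read_sim_params(), seed = 1L) {
  if (is.null(index)) {
    index <- build_kmer_index(c(master = locus$master))
  }
  if (length(deleted_exons) &&
      !all(diff(sort(deleted_exons)) == 1)) {
    stop("deleted_exons must be consecutive", call. = FALSE)
  }
  pad <- locus$params$intron_length %/% 2L
  hapA <- locus$master
  hapB <- if (length(deleted_exons) == 0) locus$master else {
    d5 <- locus$exons$start[min(deleted_exons)] - pad
    d3 <- locus$exons$end[max(deleted_exons)] + pad
    paste0(substr(locus$master, 1L, d5), substring(locus$master, d3 + 1L))
  }
  half <- coverage / 2
  prm <- reads
  pairs <- bind_rows(
    simulate_read_pairs(hapA, prm,
                        pairs_for_coverage(nchar(hapA), half, prm$outer_distance),
                        contig_name = "master", haplotype = "hapA",
                        seed = seed),
    simulate_read_pairs(hapB, prm,
                        pairs_for_coverage(nchar(hapB), half, prm$outer_distance),
                        contig_name = "master", haplotype = "hapB",
                        seed = seed + 1L)
  )
  pairs$pair_id <- seq_len(nrow(pairs))
  map_read_pairs(pairs, index, outer_distance = prm$outer_distance,
                 seed = seed + 2L)
}

#' Run a CNV recovery experiment against a simulated control panel
#'
#' Simulates `n_controls` copy-number-normal samples and one index sample
#' carrying a heterozygous deletion of the given exons, computes the
#' target coverage matrix, per-control log2 ratios and CNV calls.
#'
#' @param deleted_exons Exons deleted in the index sample (empty for a
#'   control-vs-control run).
#' @param locus A `locus_model`; default is a 30-exon master-only locus.
#' @param n_controls Control panel size.
#' @param coverage Per-sample fold coverage. The default 400x is a
#'   five-fold scale-down from the sequencing depth at which this kind of
#'   panel CNV analysis is run in production; it keeps the per-exon log2
#'   noise (sd ~ 0.08) well inside the 0.6 calling threshold even for
#'   long deletions whose ratios are shrunk towards zero by internal
#'   normalisation.
#' @param params A [cnv_params()].
#' @param index_sample Which sample to use as index: `"index"` (default)
#'   or a control id for control-vs-control specificity runs.
#' @param cohort Optional precomputed output of a previous run (reuses the
#'   control alignments).
#' @param seed Seed.
#' @return List: `calls` (a `cnv_calls` tibble), `ratios`, `covmat`,
#'   `alignments`, `locus`, `deleted_exons`.
#' @export
run_cnv_experiment <- function(deleted_exons = integer(0),
                               locus = NULL, n_controls = 6L,
                               coverage = 400, params = cnv_params(),
                               index_sample = "index", cohort = NULL,
                               seed = 1L) {
  if (is.null(locus)) {
    locus <- generate_master_locus(
      locus_params(exon_count = 30L, n_pseudogenes = 0L,
                   duplicated_exon_range = c(1L, 30L), seed = seed))
  }
  kidx <- build_kmer_index(c(master = locus$master))
  aln <- if (!is.null(cohort)) cohort$alignments else list()
  for (k in seq_len(n_controls)) {
    nm <- paste0("control", k)
    if (is.null(aln[[nm]])) {
      aln[[nm]] <- simulate_cnv_sample(locus, integer(0), coverage, kidx,
                                       seed = seed + 100L * k)
    }
  }
  if (index_sample == "index") {
    aln[["index"]] <- simulate_cnv_sample(locus, deleted_exons, coverage,
                                          kidx, seed = seed + 7L)
  }
  controls <- setdiff(grep("^control", names(aln), value = TRUE), index_sample)
  targets <- locus$exons
  covmat <- target_coverage_matrix(aln, targets,
                                   max_segment_size = params$max_segment_size)
  ratios <- normalize_and_ratio(covmat, index_sample, controls)
  calls <- call_cnv(ratios, params)
  list(calls = calls, ratios = ratios, covmat = covmat, alignments = aln,
       locus = locus, deleted_exons = deleted_exons)
}

# How far an aligner could extend an alignment across a deletion junction:
# anchored affine-gap alignment of the read continuation `a` against the
# reference continuation `b`; returns the largest reference extension
# reached with positive score.  Exact microhomology is the gapless special
# case; gapped near-homology extends junctions the same way production
# aligners do, which makes the breakpoint coordinate ambiguous.
junction_extension <- function(a, b, scheme = scoring_scheme(), L = 40L) {
  a <- strsplit(toupper(substr(a, 1, L)), "")[[1]]
  b <- strsplit(toupper(substr(b, 1, L)), "")[[1]]
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) return(0L)
  NEG <- -1e9
  go <- scheme$gap_open + scheme$gap_extend; ge <- scheme$gap_extend
  H <- matrix(NEG, m + 1, n + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in 2:(n + 1)) { E[1, j] <- max(H[1, j - 1] - go, E[1, j - 1] - ge); H[1, j] <- E[1, j] }
  for (i in 2:(m + 1)) { F[i, 1] <- max(H[i - 1, 1] - go, F[i - 1, 1] - ge); H[i, 1] <- F[i, 1] }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (a[i - 1] == b[j - 1]) scheme$match else -scheme$mismatch
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  pos <- which(H > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(0L)
  max(pos[, 2]) - 1L
}

# junction ambiguity of a planted deletion: the larger of the two
# junction-extension lengths (rightwards past the 5' breakpoint and
# leftwards past the 3' breakpoint)
junction_homology <- function(master, d5, d3, scheme = scoring_scheme()) {
  n <- nchar(master)
  rev_chr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  ext_r <- junction_extension(substr(master, d3 + 1L, min(n, d3 + 40L)),
                              substr(master, d5 + 1L, min(d3, d5 + 40L)),
                              scheme)
  ext_l <- junction_extension(rev_chr(substr(master, max(1L, d5 - 39L), d5)),
                              rev_chr(substr(master, max(d5 + 1L, d3 - 39L), d3)),
                              scheme)
  max(ext_r, ext_l)
}

#' Simulate and resolve one planted-deletion breakpoint case
#'
#' Plants a heterozygous deletion with a clean junction (at most 1 bp of
#' junction microhomology, so the truth coordinate is defined to +/-1 bp;
#' larger homology makes the breakpoint intrinsically ambiguous and real
#' callers then report a homology interval), simulates reads around the
#' junction from the deletion haplotype, maps them, clusters the
#' soft-clips and resolves the breakpoint hypothesis.
#'
#' @param master Master sequence; generated when `NULL`.
#' @param master_length Length for a generated master.
#' @param del_length Deletion length in bases (drawn uniformly from
#'   `del_range` when `NULL`).
#' @param del_range Deletion length range.
#' @param coverage Fold coverage of the junction window.
#' @param window Half-width of the simulated window around the junction.
#' @param seed Seed.
#' @return List: `truth` (`d5`, `d3`), `hypothesis` (one-row tibble from
#'   [resolve_deletion()]), `clusters`, `master`.
#' @export
simulate_breakpoint_case <- function(master = NULL, master_length = 10000L,
                                     del_length = NULL,
                                     del_range = c(500L, 5000L),
                                     coverage = 80, window = 400L,
                                     seed = 1L) {
  with_seed_if(seed, {
    if (is.null(master)) master <- random_dna(master_length)
    n <- nchar(master)
    for (attempt in 1:50) {
      dl <- del_length %||%
        as.integer(floor(runif(1, del_range[1], del_range[2] + 1)))
      d5 <- as.integer(floor(runif(1, window + 50L, n - dl - window - 50L)))
      d3 <- d5 + dl
      if (junction_homology(master, d5, d3) <= 1L) break
    }
    hap_del <- paste0(substr(master, 1L, d5), substring(master, d3 + 1L))
    # reads from the deletion haplotype around the junction
    lo <- d5 - window
    sub <- substr(hap_del, lo + 1L, d5 + window)
    prm <- read_sim_params(target_coverage = coverage, seed = seed + 1L)
    pairs <- simulate_read_pairs(sub, prm, contig_name = "master",
                                 haplotype = "hap-del", seed = seed + 1L)
    idx <- build_kmer_index(c(master = master))
    aln <- map_read_pairs(pairs, idx, seed = seed + 2L)
    clips <- extract_soft_clips(aln)
    clusters <- cluster_clips(clips[clips$side == "right", ])
    hyp <- if (nrow(clusters) == 0) NULL else {
      resolve_deletion(clusters[1, ], master)
    }
    list(truth = tibble(d5 = d5, d3 = d3), hypothesis = hyp,
         clusters = clusters, master = master)
  })
}

#' Breakpoint recovery over many planted deletions
#'
#' @param n_cases Number of planted deletions.
#' @param tolerance Recovery tolerance in bases for both endpoints.
#' @param seed Seed.
#' @param ... Passed to [simulate_breakpoint_case()].
#' @return Tibble with one row per case: truth and resolved endpoints,
#'   `recovered` flag; recovery rate in attribute `recovery_rate`.
#' @export
run_breakpoint_experiment <- function(n_cases = 50L, tolerance = 1L,
                                      seed = 1L, ...) {
  rows <- lapply(seq_len(n_cases), function(i) {
    cs <- simulate_breakpoint_case(seed = seed + 1000L * i, ...)
    h <- cs$hypothesis
    if (is.null(h)) {
      return(tibble(case = i, d5 = cs$truth$d5, d3 = cs$truth$d3,
                    bp5 = NA_integer_, bp3 = NA_integer_, recovered = FALSE))
    }
    tibble(case = i, d5 = cs$truth$d5, d3 = cs$truth$d3,
           bp5 = h$bp5, bp3 = h$bp3_start,
           recovered = abs(h$bp5 - cs$truth$d5) <= tolerance &
             abs(h$bp3_start - cs$truth$d3) <= tolerance)
  })
  out <- bind_rows(rows)
  attr(out, "recovery_rate") <- mean(out$recovered)
  out
}
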