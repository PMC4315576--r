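#' Extract soft-clipped read segments
#'
#' One record per soft-clip of at least `min_clip_len` bases. The boundary
#' is the reference coordinate of the aligned/clipped junction: for a
#' right-side clip the position one past the last aligned base, for a
#' left-side clip the first aligned base.
#'
#' @param alignments Mapped-read tibble.
#' @param min_clip_len Minimum clip length to report.
#' @return Tibble: `qname`, `contig`, `boundary` (0-based), `side`
#'   (`left`/`right`), `clip_seq`, `clip_len`, `mapq`.
#' @export
extract_soft_clips <- function(alignments, min_clip_len = 10L) {
  a <- alignments[alignments$mapped & !is.na(alignments$cigar) &
                    grepl("S", alignments$cigar, fixed = TRUE), , drop = FALSE]
  recs <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    cg <- a$cigar[i]
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    rows <- list()
    if (op[1] == "S" && len[1] >= min_clip_len) {
      rows$left <- tibble(
        qname = a$qname[i], contig = a$contig[i], boundary = a$pos[i],
        side = "left", clip_seq = substr(a$seq[i], 1L, len[1]),
        clip_len = len[1], mapq = a$mapq[i])
    }
    k <- length(op)
    if (op[k] == "S" && len[k] >= min_clip_len) {
      ref_len <- sum(len[op %in% c("M", "D", "N", "=", "X")])
      q_len <- nchar(a$seq[i])
      rows$right <- tibble(
        qname = a$qname[i], contig = a$contig[i],
        boundary = a$pos[i] + ref_len, side = "right",
        clip_seq = substr(a$seq[i], q_len - len[k] + 1L, q_len),
        clip_len = len[k], mapq = a$mapq[i])
    }
    if (length(rows)) recs[[i]] <- bind_rows(rows)
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble(qname = character(), contig = character(),
                  boundary = integer(), side = character(),
                  clip_seq = character(), clip_len = integer(),
                  mapq = integer())
  }
  out[order(out$contig, out$boundary), ]
}

#' Cluster soft-clips sharing a boundary
#'
#' Clips on the same contig and side whose boundaries lie within
#' `tolerance` of each other are merged into one cluster; the consensus of
#' the clipped sequences is taken per column by majority (ties to the
#' first-seen base), with right-side clips anchored at their left edge and
#' left-side clips at their right edge. Clusters are ranked by supporting
#' read count.
#'
#' @param clips Tibble from [extract_soft_clips()].
#' @param tolerance Maximum boundary distance within a cluster.
#' @return Tibble: `contig`, `side`, `boundary` (modal boundary), `count`,
#'   `consensus`.
#' @export
cluster_clips <- function(clips, tolerance = 0L) {
  if (nrow(clips) == 0) {
    return(tibble(contig = character(), side = character(),
                  boundary = integer(), count = integer(),
                  consensus = character()))
  }
  clips <- clips[order(clips$contig, clips$side, clips$boundary), ]
  grp <- integer(nrow(clips))
  g <- 0L
  for (i in seq_len(nrow(clips))) {
    if (i == 1 || clips$contig[i] != clips$contig[i - 1] ||
        clips$side[i] != clips$side[i - 1] ||
        clips$boundary[i] - clips$boundary[i - 1] > tolerance) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  out <- lapply(split(seq_len(nrow(clips)), grp), function(ii) {
    cc <- clips[ii, ]
    bnd <- as.integer(names(which.max(table(cc$boundary))))
    tibble(contig = cc$contig[1], side = cc$side[1], boundary = bnd,
           count = nrow(cc),
           consensus = clip_consensus(cc$clip_seq, cc$side[1]))
  })
  out <- bind_rows(out)
  out[order(-out$count), ]
}

# per-column majority consensus; ties go to the first-seen base
clip_consensus <- function(seqs, side) {
  width <- max(nchar(seqs))
  # anchor all clips at the boundary-adjacent edge
  if (side == "left") {
    seqs <- vapply(seqs, function(s)
      paste0(strrep(" ", width - nchar(s)), s), character(1))
  }
  cons <- character(width)
  mat <- do.call(rbind, lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    length(ch) <- width
    ch
  }))
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[!is.na(col) & col != " "]
    if (length(col) == 0) { cons[j] <- "N"; next }
    counts <- table(factor(col, levels = unique(col)))  # first-seen order
    cons[j] <- names(counts)[which.max(counts)]
  }
  paste(cons, collapse = "")
}

#' Place a clipped consensus on the locus by Smith-Waterman
#'
#' Aligns the unaligned (clipped) consensus against the full locus
#' sequence; the best-aligning target interval is the candidate for the
#' other endpoint of the event. A placement is confident when its score
#' reaches `min_score_frac` of the maximum attainable for the fragment;
#' below the floor, sliding-window decomposition ([window_decompose()]) is
#' the fallback.
#'
#' @param consensus Clipped consensus sequence.
#' @param locus_sequence Sequence to search (e.g. the master gene).
#' @param scheme A [scoring_scheme()].
#' @param min_score_frac Confidence floor as a fraction of the maximum
#'   score (`match * nchar(consensus)`).
#' @param max_hits Number of co-optimal placements to report.
#' @return Tibble of placements with `score`, `target_start`, `target_end`,
#'   `cigar`, `confident`, `n_best` (co-optimal placement count),
#'   `ambiguous`.
#' @export
place_clip <- function(consensus, locus_sequence, scheme = scoring_scheme(),
                       min_score_frac = 0.9, max_hits = 10L) {
  hits <- smith_waterman(consensus, locus_sequence, scheme,
                         max_hits = max_hits)
  floor_score <- min_score_frac * scheme$match * nchar(consensus)
  hits$confident <- hits$score >= floor_score
  hits$n_best <- nrow(hits)
  hits$ambiguous <- nrow(hits) > 1
  hits
}

#' Sliding-window decomposition of a clipped consensus
#'
#' Decomposes the consensus into short windows (default 20 bases, step 1),
#' places each window on the locus by Smith-Waterman, and lets the
#' extremal confidently placed windows delimit the candidate endpoint
#' interval. Used when direct placement fails, e.g. when repeat shuffling
#' at the true endpoint prevents a full-length alignment.
#'
#' @param consensus Clipped consensus sequence (>= `window` bases).
#' @param locus_sequence Sequence to search.
#' @param window Window size in bases.
#' @param step Step between windows.
#' @param scheme A [scoring_scheme()].
#' @param min_score_frac Confidence floor per window.
#' @return List with `windows` (per-window best placements:
#'   `query_start`, `target_start`, `target_end`, `score`, `confident`,
#'   `ambiguous`) and `boundary` (interval tibble delimited by the
#'   extremal confident windows, or zero rows when no window places).
#' @export
window_decompose <- function(consensus, locus_sequence, window = 20L,
                             step = 1L, scheme = scoring_scheme(),
                             min_score_frac = 0.9) {
  n <- nchar(consensus)
  if (n < window) stop("consensus shorter than one window", call. = FALSE)
  starts <- seq(0L, n - window, by = step)
  res <- lapply(starts, function(s) {
    w <- substr(consensus, s + 1L, s + window)
    if (grepl("^N+$", w)) {
      return(tibble(query_start = s, target_start = NA_integer_,
                    target_end = NA_integer_, score = 0L,
                    confident = FALSE, ambiguous = FALSE))
    }
    h <- place_clip(w, locus_sequence, scheme, min_score_frac, max_hits = 5L)
    tibble(query_start = s, target_start = h$target_start[1],
           target_end = h$target_end[1], score = h$score[1],
           confident = h$confident[1], ambiguous = h$ambiguous[1])
  })
  windows <- bind_rows(res)
  conf <- windows[windows$confident, , drop = FALSE]
  boundary <- if (nrow(conf) == 0) {
    tibble(start = integer(), end = integer())
  } else {
    tibble(start = min(conf$target_start), end = max(conf$target_end))
  }
  list(windows = windows, boundary = boundary)
}

#' Resolve a deletion breakpoint hypothesis
#'
#' Combines a soft-clip cluster (the 5' breakpoint) with the placement of
#' its clipped consensus (the 3' endpoint candidate) and checks
#' consistency against the span suggested by coverage-based CNV analysis.
#' When the placement is not confident, the consensus is decomposed in
#' sliding windows; if that also fails, the CNV-supported interval itself
#' is reported as the 3' candidate (the endpoint then lies in sequence
#' missing from the captured reference).
#'
#' @param cluster One row of [cluster_clips()] output (highest-count
#'   cluster of the event).
#' @param locus_sequence Sequence to place the clip on.
#' @param cnv_event Optional single-row `cnv_calls` tibble for the
#'   consistency check and interval fallback.
#' @param scheme A [scoring_scheme()].
#' @param min_score_frac Confidence floor for direct placement.
#' @return One-row tibble: `contig`, `bp5`, `bp3_start`, `bp3_end`,
#'   `count`, `method` (`direct-SW` / `window-decomposition` /
#'   `cnv-interval`), `n_candidates`, `ambiguous`, `cnv_consistent`.
#' @export
resolve_deletion <- function(cluster, locus_sequence, cnv_event = NULL,
                             scheme = scoring_scheme(),
                             min_score_frac = 0.9) {
  stopifnot(nrow(cluster) == 1)
  bp5 <- cluster$boundary
  hits <- place_clip(cluster$consensus, locus_sequence, scheme,
                     min_score_frac)
  method <- "direct-SW"
  if (!any(hits$confident)) {
    if (nchar(cluster$consensus) >= 20L) {
      dec <- window_decompose(cluster$consensus, locus_sequence,
                              scheme = scheme,
                              min_score_frac = min_score_frac)
      if (nrow(dec$boundary) > 0) {
        hits <- tibble(score = max(dec$windows$score),
                       target_start = dec$boundary$start,
                       target_end = dec$boundary$end,
                       confident = TRUE, n_best = 1L,
                       ambiguous = any(dec$windows$ambiguous))
        method <- "window-decomposition"
      }
    }
    if (!any(hits$confident)) {
      if (is.null(cnv_event) || nrow(cnv_event) == 0) {
        stop("clip placement failed and no CNV interval to fall back on",
             call. = FALSE)
      }
      hits <- tibble(score = NA_integer_, target_start = cnv_event$start,
                     target_end = cnv_event$end, confident = FALSE,
                     n_best = 1L, ambiguous = TRUE)
      method <- "cnv-interval"
    }
  }
  # the clip consensus continues from the 3' breakpoint: for a right-side
  # clip its placement start is the first retained base after the deletion
  bp3_start <- min(hits$target_start)
  bp3_end <- max(hits$target_start)
  if (cluster$side == "right" && bp3_start < bp5 && method == "direct-SW") {
    stop("clip places upstream of the 5' boundary; not a deletion",
         call. = FALSE)
  }
  consistent <- if (is.null(cnv_event) || nrow(cnv_event) == 0) NA else {
    bp5 >= cnv_event$start - 500L && bp3_end <= cnv_event$end + 500L
  }
  tibble(contig = cluster$contig, bp5 = bp5,
         bp3_start = bp3_start, bp3_end = bp3_end,
         count = cluster$count, method = method,
         n_candidates = nrow(hits), ambiguous = any(hits$ambiguous),
         cnv_consistent = consistent)
}

#' Write a breakpoint report
#' @param hypotheses Tibble of [resolve_deletion()] rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_breakpoint_report <- function(hypotheses, path) {
  readr::write_tsv(hypotheses, path)
  invisible(path)
}
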