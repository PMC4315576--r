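#' CNV-calling parameters
#'
#' Depth-ratio thresholds and the named filter ledger. A copy-number event
#' passes when its log2 depth ratio clears +/-0.6 against at least 85% of
#' the control panel; events supported by 50-85% of controls are
#' "indicated" only. The ledger regions name the exons excluded from
#' reporting: critical exons with restricted discriminative mapping,
#' recurrent artifact exons, and exons with insufficient or varying
#' coverage.
#'
#' @param log2_amp Amplification threshold (>= 0.6).
#' @param log2_del Deletion threshold (<= -0.6).
#' @param support_pass Minimum control-support fraction for a pass call.
#' @param support_indicated Lower bound of the "indicated" band.
#' @param max_segment_size Targets longer than this are split into
#'   equal-size subsegments before analysis.
#' @param critical_regions,artifact_regions,lowcov_regions Named interval
#'   tibbles (see [intervals()]) for the filter ledger; `NULL` disables a
#'   ledger class.
#' @param min_controls Minimum usable control panel size; fewer is an
#'   error, fewer than `warn_controls` a warning.
#' @param warn_controls Panel size below which a warning is issued.
#' @return A `cnv_params` list.
#' @export
cnv_params <- function(log2_amp = 0.6, log2_del = -0.6,
                       support_pass = 0.85, support_indicated = 0.50,
                       max_segment_size = 300L,
                       critical_regions = NULL, artifact_regions = NULL,
                       lowcov_regions = NULL,
                       min_controls = 3L, warn_controls = 6L) {
  if (!(support_indicated < support_pass && support_pass <= 1)) {
    stop("need support_indicated < support_pass <= 1", call. = FALSE)
  }
  if (!(log2_del < 0 && log2_amp > 0)) {
    stop("need log2_del < 0 < log2_amp", call. = FALSE)
  }
  structure(list(log2_amp = log2_amp, log2_del = log2_del,
                 support_pass = support_pass,
                 support_indicated = support_indicated,
                 max_segment_size = as.integer(max_segment_size),
                 critical_regions = critical_regions,
                 artifact_regions = artifact_regions,
                 lowcov_regions = lowcov_regions,
                 min_controls = as.integer(min_controls),
                 warn_controls = as.integer(warn_controls)),
            class = "cnv_params")
}

#' Split targets longer than a maximum segment size
#'
#' @param targets Interval tibble.
#' @param max_segment_size Maximum segment length.
#' @return Interval tibble with long targets split into near-equal pieces;
#'   `target_id` identifies each segment.
#' @export
split_targets <- function(targets, max_segment_size = 300L) {
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("target", seq_len(nrow(targets)))
  }
  pieces <- lapply(seq_len(nrow(targets)), function(i) {
    len <- targets$end[i] - targets$start[i]
    k <- ceiling(len / max_segment_size)
    cuts <- targets$start[i] + round(seq(0, len, length.out = k + 1))
    tibble(contig = targets$contig[i],
           start = as.integer(cuts[-length(cuts)]),
           end = as.integer(cuts[-1]),
           name = if (k == 1) targets$name[i] else
             paste0(targets$name[i], ".", seq_len(k)))
  })
  out <- bind_rows(pieces)
  out$target_id <- seq_len(nrow(out))
  out
}

#' Mean per-base depth of each target in each sample
#'
#' @param alignments_list Named list of mapped-read tibbles, one per
#'   sample (the names become sample ids).
#' @param targets Interval tibble of target regions (disjoint).
#' @param max_segment_size Passed to [split_targets()].
#' @return A long coverage tibble: `sample`, `target_id`, `name`,
#'   `contig`, `start`, `end`, `mean_depth`.
#' @export
target_coverage_matrix <- function(alignments_list, targets,
                                   max_segment_size = 300L) {
  stopifnot(length(alignments_list) >= 1)
  if (is.null(names(alignments_list))) {
    names(alignments_list) <- paste0("sample", seq_along(alignments_list))
  }
  tg <- split_targets(targets, max_segment_size)
  out <- lapply(names(alignments_list), function(s) {
    a <- alignments_list[[s]]
    a <- a[a$mapped, , drop = FALSE]
    md <- rep(0, nrow(tg))
    for (ct in unique(tg$contig)) {
      sel <- tg$contig == ct
      ac <- a[a$contig == ct, , drop = FALSE]
      lo <- min(tg$start[sel]); hi <- max(tg$end[sel])
      ends <- ac$pos + cigar_ref_length(ac$cigar)
      cov <- cpp_span_coverage(ac$pos, as.integer(ends), lo, hi)
      md[sel] <- vapply(which(sel), function(i) {
        mean(cov[(tg$start[i] - lo + 1L):(tg$end[i] - lo)])
      }, double(1))
    }
    tibble(sample = s, target_id = tg$target_id, name = tg$name,
           contig = tg$contig, start = tg$start, end = tg$end,
           mean_depth = md)
  })
  bind_rows(out)
}

#' Internally normalise samples and form per-control log2 ratios
#'
#' Each sample is scaled so that its mean target depth is 1 (internal
#' normalisation), then the index sample is compared against every control
#' separately: `log2(index / control)` per target per control. Targets at
#' which a control has zero depth get an undefined ratio and are flagged
#' low-coverage.
#'
#' @param covmat Long coverage tibble from [target_coverage_matrix()].
#' @param index_sample Sample id of the sample of interest.
#' @param control_samples Character vector of control sample ids (default:
#'   all other samples).
#' @return Tibble: `target_id`, `name`, `contig`, `start`, `end`,
#'   `control`, `log2_ratio`, `lowcov`.
#' @export
normalize_and_ratio <- function(covmat, index_sample,
                                control_samples = NULL) {
  samples <- unique(covmat$sample)
  if (!index_sample %in% samples) stop("unknown index sample", call. = FALSE)
  control_samples <- control_samples %||% setdiff(samples, index_sample)
  norm <- covmat |>
    group_by(.data$sample) |>
    mutate(norm_depth = .data$mean_depth / mean(.data$mean_depth)) |>
    ungroup()
  idx <- norm[norm$sample == index_sample, ]
  out <- lapply(control_samples, function(cs) {
    ctl <- norm[norm$sample == cs, ]
    m <- match(idx$target_id, ctl$target_id)
    lowcov <- ctl$norm_depth[m] == 0
    tibble(target_id = idx$target_id, name = idx$name, contig = idx$contig,
           start = idx$start, end = idx$end, control = cs,
           log2_ratio = ifelse(lowcov, NA_real_,
                               log2(idx$norm_depth / ctl$norm_depth[m])),
           lowcov = lowcov)
  })
  bind_rows(out)
}

#' Call copy-number events from per-control log2 ratios
#'
#' For each target and direction, the control-support fraction is the
#' share of controls whose ratio clears the direction's log2 threshold.
#' Targets reach `pass` status at support >= `support_pass` and
#' `indicated` status in the 50-85% band. Adjacent same-direction targets
#' in either band are merged into one event whose status is `pass` when
#' at least one member target passes: a multi-exon deletion detected at a
#' passing anchor exon has its full extent read off the 50%-support band
#' (internal normalisation shrinks per-exon ratios as the event grows, so
#' distal exons of a long deletion often reach only the indicated band).
#'
#' @param ratios Tibble from [normalize_and_ratio()].
#' @param params A [cnv_params()].
#' @return A `cnv_calls` tibble: one row per event with `contig`, `start`,
#'   `end`, `targets` (list of target names), `n_targets`, `direction`,
#'   `median_log2`, `support_fraction`, `status`, `filter_reasons` (list,
#'   empty until [apply_filter_ledger()]). The per-target table is kept in
#'   attribute `per_target`.
#' @export
call_cnv <- function(ratios, params = cnv_params()) {
  n_controls <- length(unique(ratios$control))
  if (n_controls < params$min_controls) {
    stop("need at least ", params$min_controls, " controls", call. = FALSE)
  }
  if (n_controls < params$warn_controls) {
    warning("control panel smaller than ", params$warn_controls, " samples",
            call. = FALSE)
  }
  per_target <- ratios |>
    group_by(.data$target_id, .data$name, .data$contig, .data$start, .data$end) |>
    summarise(
      support_del = mean(.data$log2_ratio <= params$log2_del, na.rm = TRUE),
      support_amp = mean(.data$log2_ratio >= params$log2_amp, na.rm = TRUE),
      median_log2 = median(.data$log2_ratio, na.rm = TRUE),
      any_lowcov = any(.data$lowcov),
      .groups = "drop"
    ) |>
    mutate(
      direction = ifelse(.data$support_del >= .data$support_amp, "del", "amp"),
      support_fraction = pmax(.data$support_del, .data$support_amp),
      status = dplyr::case_when(
        .data$support_fraction >= params$support_pass ~ "pass",
        .data$support_fraction >= params$support_indicated ~ "indicated",
        TRUE ~ "none"
      )
    ) |>
    arrange(.data$contig, .data$start)

  hits <- per_target[per_target$status != "none", , drop = FALSE]
  calls <- if (nrow(hits) == 0) {
    tibble(contig = character(), start = integer(), end = integer(),
           targets = list(), n_targets = integer(), direction = character(),
           median_log2 = double(), support_fraction = double(),
           status = character())
  } else {
    # merge runs of adjacent same-direction targets; a passing anchor
    # carries the whole run to pass status
    hits <- hits[order(hits$contig, hits$start), ]
    new_run <- c(TRUE, !(hits$contig[-1] == hits$contig[-nrow(hits)] &
                           hits$direction[-1] == hits$direction[-nrow(hits)] &
                           hits$target_id[-1] == hits$target_id[-nrow(hits)] + 1L))
    hits$run <- cumsum(new_run)
    hits |>
      group_by(.data$run) |>
      summarise(
        contig = .data$contig[1], start = min(.data$start), end = max(.data$end),
        targets = list(.data$name), n_targets = n(),
        direction = .data$direction[1],
        median_log2 = median(.data$median_log2),
        support_fraction = min(.data$support_fraction),
        status = if (any(.data$status == "pass")) "pass" else "indicated",
        .groups = "drop"
      ) |>
      select(-"run")
  }
  calls$filter_reasons <- rep(list(character()), nrow(calls))
  calls <- calls[, c("contig", "start", "end", "targets", "n_targets",
                     "direction", "median_log2", "support_fraction",
                     "status", "filter_reasons")]
  class(calls) <- c("cnv_calls", class(calls))
  attr(calls, "per_target") <- per_target
  attr(calls, "n_controls") <- n_controls
  calls
}

overlaps_any <- function(calls, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, nrow(calls)))
  hit <- rep(FALSE, nrow(calls))
  for (ct in unique(regions$contig)) {
    rg <- regions[regions$contig == ct, ]
    sel <- which(calls$contig == ct)
    if (!length(sel)) next
    q <- IRanges::IRanges(calls$start[sel] + 1L, calls$end[sel])
    s <- IRanges::IRanges(rg$start + 1L, rg$end)
    hit[sel] <- hit[sel] | IRanges::overlapsAny(q, s)
  }
  hit
}

#' Apply the named filter ledger to CNV calls
#'
#' Marks calls overlapping critical, artifact, or low-coverage ledger
#' regions, and deletion calls containing heterozygous variant evidence
#' (a true heterozygous deletion cannot show heterozygous sites inside the
#' deleted span). Reasons are a set: applying the filters in any order
#' gives the same final status.
#'
#' @param calls A `cnv_calls` tibble.
#' @param params A [cnv_params()] with ledger regions.
#' @param het_variant_evidence Optional calls tibble; standard-tier het
#'   calls with alt fraction in `het_band` inside a deletion span trigger
#'   the het-evidence filter.
#' @param het_band Alt-fraction band that counts as het evidence.
#' @return The calls with `status = "filtered"` and named
#'   `filter_reasons` where any ledger rule fires.
#' @export
apply_filter_ledger <- function(calls, params = cnv_params(),
                                het_variant_evidence = NULL,
                                het_band = c(0.20, 0.80)) {
  reasons <- list(
    `critical-region` = overlaps_any(calls, params$critical_regions),
    `artifact-region` = overlaps_any(calls, params$artifact_regions),
    `lowcov-region` = overlaps_any(calls, params$lowcov_regions)
  )
  het_hit <- rep(FALSE, nrow(calls))
  if (!is.null(het_variant_evidence) && nrow(het_variant_evidence) > 0) {
    ev <- het_variant_evidence
    ev <- ev[ev$zygosity == "het" & ev$tier == "standard" &
               ev$alt_fraction >= het_band[1] & ev$alt_fraction <= het_band[2], ]
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(calls))) {
        if (calls$direction[i] != "del") next
        het_hit[i] <- any(ev$contig == calls$contig[i] &
                            ev$pos >= calls$start[i] & ev$pos < calls$end[i])
      }
    }
  }
  reasons$`het-evidence` <- het_hit
  for (i in seq_len(nrow(calls))) {
    r <- sort(names(reasons)[vapply(reasons, `[`, logical(1), i)])
    calls$filter_reasons[[i]] <- r
    if (length(r) > 0) calls$status[i] <- "filtered"
  }
  calls
}

#' MLPA-style relative-peak-area ratios
#'
#' Ratio of a sample's relative peak area (RPA) to the control mean per
#' probe; a probe is flagged as deleted when the ratio falls strictly
#' below 75%. Probes with zero control RPA are flagged undefined.
#'
#' @param sample_rpa Named numeric vector (or tibble `probe`, `rpa`) of the
#'   sample's per-probe RPA values.
#' @param control_rpa Matching per-probe control mean RPA.
#' @param deletion_threshold Ratio below which a deletion is indicated.
#' @return Tibble: `probe`, `ratio`, `deletion`, `undefined`.
#' @export
mlpa_ratio <- function(sample_rpa, control_rpa, deletion_threshold = 0.75) {
  if (is.data.frame(sample_rpa)) {
    sample_rpa <- setNames(sample_rpa$rpa, sample_rpa$probe)
  }
  if (is.data.frame(control_rpa)) {
    control_rpa <- setNames(control_rpa$rpa, control_rpa$probe)
  }
  if (is.null(names(sample_rpa))) names(sample_rpa) <- seq_along(sample_rpa)
  if (is.null(names(control_rpa))) names(control_rpa) <- seq_along(control_rpa)
  if (!setequal(names(sample_rpa), names(control_rpa))) {
    stop("probe sets differ between sample and controls", call. = FALSE)
  }
  ctl <- control_rpa[names(sample_rpa)]
  undef <- ctl == 0
  ratio <- ifelse(undef, NA_real_, sample_rpa / ctl)
  tibble(probe = names(sample_rpa), ratio = unname(ratio),
         deletion = !is.na(ratio) & ratio < deletion_threshold,
         undefined = unname(undef))
}

#' Per-target coverage quality control
#'
#' @param alignments Mapped-read tibble for one sample.
#' @param targets Interval tibble.
#' @param floor Depth adequacy floor (default 20x).
#' @return Tibble per target: `name`, `contig`, `start`, `end`,
#'   `mean_depth`, `fraction_at_floor` (share of bases >= floor), `lowcov`
#'   flag. Aggregate statistics are in attribute `aggregate`.
#' @export
coverage_qc <- function(alignments, targets, floor = 20L) {
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("target", seq_len(nrow(targets)))
  }
  a <- alignments[alignments$mapped, , drop = FALSE]
  res <- lapply(seq_len(nrow(targets)), function(i) {
    ac <- a[a$contig == targets$contig[i], , drop = FALSE]
    ends <- ac$pos + cigar_ref_length(ac$cigar)
    cov <- cpp_span_coverage(ac$pos, as.integer(ends),
                             targets$start[i], targets$end[i])
    tibble(name = targets$name[i], contig = targets$contig[i],
           start = targets$start[i], end = targets$end[i],
           mean_depth = mean(cov),
           fraction_at_floor = if (length(cov)) mean(cov >= floor) else 0)
  })
  out <- bind_rows(res)
  out$lowcov <- out$fraction_at_floor < 1
  attr(out, "aggregate") <- tibble(
    mean_depth = mean(out$mean_depth),
    fraction_targets_fully_covered = mean(!out$lowcov),
    fraction_bases_at_floor =
      sum(out$fraction_at_floor * (out$end - out$start)) /
        sum(out$end - out$start),
    floor = floor
  )
  out
}

#' Write CNV calls as tab-delimited report
#' @param calls A `cnv_calls` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cnv_report <- function(calls, path) {
  flat <- calls
  flat$targets <- vapply(flat$targets, paste, character(1), collapse = ",")
  flat$filter_reasons <- vapply(flat$filter_reasons, paste, character(1),
                                collapse = ",")
  readr::write_tsv(flat, path)
  invisible(path)
}
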