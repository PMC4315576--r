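#' Evaluation parameters
#'
#' @param flank Intronic flank (bases) around each exon included in the
#'   comparison region (exonic regions +/- 30 bp by default).
#' @param count_relaxed_tier Count relaxed-candidate calls towards
#'   sensitivity (off by default: candidates require orthogonal
#'   confirmation before they count).
#' @return An `eval_params` list.
#' @export
eval_params <- function(flank = 30L, count_relaxed_tier = FALSE) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  structure(list(flank = as.integer(flank),
                 count_relaxed_tier = count_relaxed_tier),
            class = "eval_params")
}

#' Left-normalise anchored variants
#'
#' Shifts anchored indels to their leftmost equivalent representation
#' against the reference sequence, so call/truth matching is
#' representation-independent. SNVs are returned unchanged.
#'
#' @param variants Tibble with `pos`, `ref`, `alt` (anchored; 0-based).
#' @param reference_seq Reference sequence the coordinates refer to.
#' @return The variants with normalised `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(variants, reference_seq) {
  last_ch <- function(x) substr(x, nchar(x), nchar(x))
  for (i in seq_len(nrow(variants))) {
    ref <- variants$ref[i]; alt <- variants$alt[i]; pos <- variants$pos[i]
    if (nchar(ref) == nchar(alt)) next
    while ((nchar(ref) > 1 || nchar(alt) > 1) &&
           last_ch(ref) == last_ch(alt) && pos > 0) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      if (!nzchar(ref) || !nzchar(alt)) {
        prev <- substr(reference_seq, pos, pos)  # base at 0-based pos - 1
        ref <- paste0(prev, ref); alt <- paste0(prev, alt)
        pos <- pos - 1L
      }
    }
    variants$pos[i] <- pos; variants$ref[i] <- ref; variants$alt[i] <- alt
  }
  variants
}

#' Compare calls to a truth set within the evaluation region
#'
#' The evaluation region is the exons dilated by the flank; truth variants
#' and calls outside it are excluded. A call matches a truth variant when
#' position and alleles agree after left-normalisation; a same-type call
#' within one base of an unmatched truth variant is reported as a
#' near-miss discordance, not a true positive. Zygosity concordance is
#' reported separately and does not affect the match. The true-negative
#' universe for the per-site specificity is every evaluated reference
#' position carrying neither a truth variant nor a call; the per-variant
#' specificity (TP / (TP + FP)) is also reported since printed
#' specificities rarely state their universe.
#'
#' @param calls Calls tibble (either tier).
#' @param truth A `truth_set`.
#' @param exons Interval tibble of exons.
#' @param params An [eval_params()].
#' @param reference_seq Optional reference sequence enabling
#'   left-normalisation and a ref-allele consistency check.
#' @param contig_length Used to clip the dilated evaluation region.
#' @return An `eval_report` list: `counts` (TP/FP/FN/TN), `sensitivity`,
#'   `specificity_per_site`, `precision`, `zygosity_concordance`,
#'   `per_variant` (status of every evaluated truth variant),
#'   `false_positives`, `evaluated_positions`.
#' @export
compare_to_truth <- function(calls, truth, exons, params = eval_params(),
                             reference_seq = NULL, contig_length = Inf) {
  region <- dilate_intervals(exons, params$flank, contig_length)
  if (!is.null(reference_seq) && nrow(truth) > 0) {
    obs <- substring(reference_seq, truth$pos + 1L,
                     truth$pos + nchar(truth$ref))
    if (any(obs != truth$ref)) {
      stop("truth ref alleles do not match the reference; ",
           "coordinate systems differ", call. = FALSE)
    }
    truth <- left_normalize(truth, reference_seq)
    calls <- left_normalize(calls, reference_seq)
  }
  truth_in <- truth[pos_in_intervals(truth$pos, region), , drop = FALSE]
  calls_in <- calls[pos_in_intervals(calls$pos, region), , drop = FALSE]
  if (!params$count_relaxed_tier && "tier" %in% names(calls_in)) {
    calls_in <- calls_in[calls_in$tier == "standard", , drop = FALSE]
  }

  key <- function(x) paste(x$pos, x$ref, x$alt)
  matched <- match(key(truth_in), key(calls_in))
  status <- ifelse(is.na(matched), "FN", "TP")
  # near-miss: unmatched truth with a same-type call within +/-1 bp
  near <- rep(FALSE, nrow(truth_in))
  for (i in which(is.na(matched))) {
    near[i] <- any(abs(calls_in$pos - truth_in$pos[i]) <= 1 &
                     calls_in$type == truth_in$type[i])
  }
  status[near] <- "near-miss"
  zyg_conc <- ifelse(is.na(matched), NA,
                     calls_in$zygosity[matched] == truth_in$zygosity)
  per_variant <- truth_in
  per_variant$status <- status
  per_variant$zygosity_concordant <- zyg_conc
  per_variant$called_fraction <- ifelse(is.na(matched), NA_real_,
                                        calls_in$alt_fraction[matched])

  fp <- calls_in[!key(calls_in) %in% key(truth_in), , drop = FALSE]
  n_eval <- sum(region$end - region$start)
  tp <- sum(status == "TP")
  fn <- sum(status != "TP")
  fpn <- nrow(fp)
  tn <- n_eval - length(unique(c(truth_in$pos, calls_in$pos)))
  counts <- tibble(TP = tp, FP = fpn, FN = fn, TN = tn)
  structure(list(
    counts = counts,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity_per_site = if (tn + fpn == 0) NA_real_ else tn / (tn + fpn),
    precision = if (tp + fpn == 0) NA_real_ else tp / (tp + fpn),
    zygosity_concordance = if (tp == 0) NA_real_ else
      mean(zyg_conc[status == "TP"]),
    per_variant = per_variant,
    false_positives = fp,
    evaluated_positions = n_eval,
    params = params
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d (over %d evaluated positions)\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN,
              x$evaluated_positions))
  cat(sprintf("  sensitivity %.4f  specificity (per-site) %.4f\n",
              x$sensitivity, x$specificity_per_site))
  invisible(x)
}

#' Detection-rate table
#'
#' Formats validation tallies the way diagnostic validation studies print
#' them: per category, the number of variants, the number detected, and
#' the detection rate as a percentage with one decimal (integer
#' percentages print without a decimal).
#'
#' @param tallies Tibble or data frame with columns `category`, `total`,
#'   `detected` (or a list of `(category, total, detected)` vectors).
#' @return Tibble with `category`, `total`, `detected`, `rate` (fraction),
#'   `rate_percent` (rounded to 1 decimal), `rate_label`.
#' @export
detection_rate_table <- function(tallies) {
  if (!is.data.frame(tallies)) {
    tallies <- as_tibble(do.call(rbind, lapply(tallies, function(x)
      data.frame(category = x[[1]], total = as.integer(x[[2]]),
                 detected = as.integer(x[[3]])))))
  }
  if (any(tallies$detected > tallies$total)) {
    stop("detected exceeds total in a tally row", call. = FALSE)
  }
  rate <- tallies$detected / tallies$total
  tibble(category = tallies$category, total = tallies$total,
         detected = tallies$detected, rate = rate,
         rate_percent = round(100 * rate, 1),
         rate_label = ifelse(rate == round(rate, 2) & 100 * rate == round(100 * rate),
                             sprintf("%d%%", as.integer(round(100 * rate))),
                             sprintf("%.1f%%", 100 * rate)))
}

#' Configuration for the end-to-end validation experiment
#'
#' Defaults reproduce the study conditions of the validating read
#' simulation: a 33-exon master whose full exon span is duplicated into
#' six pseudogenes at 97.7% identity, 2 x 150 bp pairs at outer distance
#' 200 and error rate 0.001, 1000-fold fragment coverage, at least one
#' planted variant per 100 bp of coding sequence, and 20 additional
#' variants planted to match pseudogene alleles (the critical-site class).
#'
#' @param locus A [locus_params()].
#' @param reads A [read_sim_params()].
#' @param thresholds A [calling_thresholds()].
#' @param evaluation An [eval_params()].
#' @param n_matched Number of pseudogene-matching variants to plant.
#' @param density_mode,mutation_rate Passed to [plant_variants()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `validation_config` list.
#' @export
validation_config <- function(locus = locus_params(),
                              reads = read_sim_params(),
                              thresholds = calling_thresholds(),
                              evaluation = eval_params(),
                              n_matched = 20L,
                              density_mode = "per-100bp",
                              mutation_rate = 0.02,
                              seed = 1L) {
  structure(list(locus = locus, reads = reads, thresholds = thresholds,
                 evaluation = evaluation, n_matched = as.integer(n_matched),
                 density_mode = density_mode, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "validation_config")
}

#' Run the end-to-end validation experiment
#'
#' Simulates the locus, plants truth variants (a divergent-position class
#' whose alternative alleles cannot coincide with pseudogene alleles, and
#' a pseudogene-matching class at divergence sites), simulates reads
#' (master haplotypes carry the variants; pseudogenes are wild-type),
#' maps them with the built-in mapper against the combined reference,
#' runs the two-step screen on the master pileup, and scores the result
#' against truth. Fully reproducible from `config$seed`.
#'
#' @param config A [validation_config()].
#' @param output_dir Optional directory to write intermediates (FASTA,
#'   BED, truth VCF, calls VCF, report TSV).
#' @return A `validation_experiment` list: `report` (eval_report over the
#'   divergent class), `report_all` (both classes), `calls`, `candidates`,
#'   `critical_sites`, `matched_sites` (observed fractions of the
#'   pseudogene-matching class), `truth`, `locus`, `config`.
#' @export
run_validation_experiment <- function(config = validation_config(),
                                      output_dir = NULL) {
  seed <- config$seed
  lp <- config$locus
  lp$seed <- seed
  locus <- generate_master_locus(lp)
  locus <- derive_pseudogenes(locus)
  truth_div <- plant_variants(locus, density_mode = config$density_mode,
                              mutation_rate = config$mutation_rate,
                              seed = seed + 2L)
  truth_mat <- if (config$n_matched > 0 && nrow(locus$divergence) > 0) {
    plant_matched_variants(locus, n = config$n_matched, seed = seed + 3L)
  } else {
    truth_div[0, ]
  }
  # matching-class sites displace any divergent-class variant too close by
  truth_div <- truth_div[!vapply(truth_div$pos, function(p)
    any(abs(p - truth_mat$pos) < 5L), logical(1)), , drop = FALSE]
  # the two classes are phased onto separate haplotypes so that a read can
  # never carry a divergent-class alternative allele together with a
  # pseudogene-matching one: with both on one fragment the pseudogene
  # outscores the master and the divergent variant is dragged down too
  # (the coupling seen between neighbouring real and simulated critical
  # sites); separating them keeps the per-class effects identifiable
  truth <- new_truth_set(bind_rows(
    mutate(truth_div, class = "divergent", haplotype = 1L),
    mutate(truth_mat, class = "pseudogene-matching", haplotype = 2L)
  ) |> arrange(.data$pos))

  pairs <- simulate_locus_reads(locus, truth, config$reads, seed = seed + 10L)
  index <- build_kmer_index(locus)
  aln <- map_read_pairs(pairs, index,
                        outer_distance = config$reads$outer_distance,
                        seed = seed + 20L)
  pileup <- build_pileup(aln, locus, thresholds = config$thresholds)
  screen <- two_step_screen(pileup, locus$duplicated, config$thresholds,
                            always_screen = TRUE)
  calls <- screen$standard
  candidates <- screen$relaxed_candidates

  div <- truth[truth$class == "divergent", , drop = FALSE]
  mat <- truth[truth$class == "pseudogene-matching", , drop = FALSE]
  # class-specific report: correctly called matching-class variants must
  # not surface as false positives of the divergent-class comparison
  calls_div <- anti_join(calls, mat[, c("pos", "ref", "alt")],
                         by = c("pos", "ref", "alt"))
  report <- compare_to_truth(calls_div, div, locus$exons, config$evaluation,
                             reference_seq = locus$master,
                             contig_length = nchar(locus$master))
  report_all <- compare_to_truth(calls, truth, locus$exons,
                                 config$evaluation,
                                 reference_seq = locus$master,
                                 contig_length = nchar(locus$master))
  critical <- detect_critical_sites(truth, bind_rows(calls, candidates),
                                    pileup, config$thresholds,
                                    reference_seq = locus$master)
  matched_sites <- observed_alt_fractions(mat, pileup, locus$master)
  matched_sites$depressed <- !is.na(matched_sites$observed_fraction) &
    matched_sites$observed_fraction < 0.45

  if (!is.null(output_dir)) {
    paths <- write_locus(locus, output_dir, truth = truth)
    write_calls_vcf(calls, file.path(output_dir, "calls.vcf"),
                    contig_length = nchar(locus$master))
    readr::write_tsv(matched_sites, file.path(output_dir, "matched_sites.tsv"))
  }

  structure(list(report = report, report_all = report_all,
                 calls = calls, candidates = candidates,
                 critical_sites = critical, matched_sites = matched_sites,
                 truth = truth, locus = locus, config = config),
            class = "validation_experiment")
}

#' @export
print.validation_experiment <- function(x, ...) {
  cat("<validation_experiment>\n")
  cat(sprintf("  planted: %d divergent + %d pseudogene-matching variants\n",
              sum(x$truth$class == "divergent"),
              sum(x$truth$class == "pseudogene-matching")))
  cat(sprintf("  standard-tier sensitivity (divergent class): %.4f\n",
              x$report$sensitivity))
  cat(sprintf("  depressed pseudogene-matching sites: %d of %d\n",
              sum(x$matched_sites$depressed), nrow(x$matched_sites)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# broom-style methods

#' Tidy an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-variant status tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_variant

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of counts and rates.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$counts, tibble(
    sensitivity = x$sensitivity,
    specificity_per_site = x$specificity_per_site,
    precision = x$precision,
    zygosity_concordance = x$zygosity_concordance,
    evaluated_positions = x$evaluated_positions))
}

#' Tidy a validation experiment
#' @param x A `validation_experiment`.
#' @param ... Unused.
#' @return Per-variant status tibble including the variant class.
#' @export
tidy.validation_experiment <- function(x, ...) {
  tidy(x$report_all)
}

#' One-row summary of a validation experiment
#' @param x A `validation_experiment`.
#' @param ... Unused.
#' @return One-row tibble with headline metrics.
#' @export
glance.validation_experiment <- function(x, ...) {
  dplyr::bind_cols(glance(x$report), tibble(
    n_truth_divergent = sum(x$truth$class == "divergent"),
    n_truth_matching = sum(x$truth$class == "pseudogene-matching"),
    n_relaxed_candidates = nrow(x$candidates),
    n_critical_sites = nrow(x$critical_sites),
    n_depressed_sites = sum(x$matched_sites$depressed)))
}

#' Tidy CNV calls
#' @param x A `cnv_calls` tibble.
#' @param ... Unused.
#' @return The per-target statistics tibble.
#' @export
tidy.cnv_calls <- function(x, ...) attr(x, "per_target")

#' One-row summary of CNV calls
#' @param x A `cnv_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble of event counts by status.
#' @export
glance.cnv_calls <- function(x, ...) {
  tibble(n_events = nrow(x),
         n_pass = sum(x$status == "pass"),
         n_indicated = sum(x$status == "indicated"),
         n_filtered = sum(x$status == "filtered"),
         n_controls = attr(x, "n_controls") %||% NA_integer_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
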