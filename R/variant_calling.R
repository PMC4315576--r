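#' Variant-calling thresholds
#'
#' The tiered allele-fraction rules for a gene with pseudogene shadowing:
#' a variant is reported when at least 20% of the total reads at the
#' position carry the alteration, called homozygous at >= 85%, and in a
#' second-step screen of the duplicated region only, the detection
#' threshold is relaxed to >= 8% to surface candidates for orthogonal
#' confirmation. The alternative-allele fraction denominator is the total
#' filtered depth, not ref + alt.
#'
#' @param standard_alt_fraction Standard detection threshold.
#' @param relaxed_alt_fraction Second-step threshold (duplicated region
#'   only).
#' @param hom_fraction Homozygous-call threshold.
#' @param min_depth Minimum depth for a site to be callable; shallower
#'   sites are reported as uncovered rather than silently negative.
#' @param min_base_quality Phred floor; bases below it are excluded from
#'   depth.
#' @param min_mapping_quality Mapping-quality floor; 0 disables the filter
#'   (the default, since discriminating read pairs at pseudogene-identical
#'   sites often carry MAPQ 0 and filtering them removes true signal
#'   except at fully identical sites).
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(standard_alt_fraction = 0.20,
                               relaxed_alt_fraction = 0.08,
                               hom_fraction = 0.85,
                               min_depth = 20L,
                               min_base_quality = 13L,
                               min_mapping_quality = 0L) {
  if (!(relaxed_alt_fraction < standard_alt_fraction &&
        standard_alt_fraction < hom_fraction && hom_fraction <= 1)) {
    stop("thresholds must satisfy relaxed < standard < hom <= 1", call. = FALSE)
  }
  structure(list(standard_alt_fraction = standard_alt_fraction,
                 relaxed_alt_fraction = relaxed_alt_fraction,
                 hom_fraction = hom_fraction,
                 min_depth = as.integer(min_depth),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality)),
            class = "calling_thresholds")
}

#' Build a per-position pileup from alignments
#'
#' Walks each CIGAR and tallies, per reference position, the filtered
#' depth and the count of every observed allele. Substitutions are keyed
#' by base; a deletion of L bases is keyed `"-L"` at its anchor (the base
#' before the deleted run) and an insertion by `"+SEQ"` at the preceding
#' base, so indel alleles share the VCF anchored representation. At an
#' anchor, a read carrying the indel votes for the indel allele instead of
#' its anchor base, which keeps the per-site allele counts summing to the
#' depth. Bases below the base-quality floor and reads below the
#' mapping-quality floor are excluded from depth and counted separately.
#'
#' @param alignments Mapped-read tibble ([map_read_pairs()] or
#'   [load_alignments()]).
#' @param reference Named character vector of contig sequences (or a
#'   `locus_model` / `kmer_index`).
#' @param region Interval tibble (single row) to pile up; default is the
#'   whole first contig.
#' @param thresholds A [calling_thresholds()] (for the quality floors).
#' @return A long pileup tibble: one row per observed allele per position
#'   (`contig`, `pos`, `ref`, `depth`, `n_lowbq`, `n_lowmq`, `allele`,
#'   `count`, `is_ref`). Positions with zero depth keep a single `NA`
#'   allele row so coverage gaps remain visible.
#' @export
build_pileup <- function(alignments, reference, region = NULL,
                         thresholds = calling_thresholds()) {
  if (inherits(reference, "locus_model")) reference <- locus_reference(reference)
  if (inherits(reference, "kmer_index")) reference <- attr(reference, "reference")
  if (is.null(region)) {
    region <- intervals(names(reference)[1], 0L, nchar(reference[1]))
  }
  stopifnot(nrow(region) == 1)
  contig <- region$contig
  if (!contig %in% names(reference)) stop("unknown contig ", contig, call. = FALSE)
  if (region$start < 0 || region$end > nchar(reference[[contig]])) {
    stop("region outside reference bounds", call. = FALSE)
  }
  a <- alignments[alignments$mapped & alignments$contig == contig, , drop = FALSE]
  qual <- if ("qual" %in% names(a)) a$qual else character(0)
  res <- cpp_pileup(reference[[contig]], a$pos, a$cigar, a$seq,
                    as.integer(a$mapq), qual,
                    region$start, region$end,
                    thresholds$min_base_quality,
                    thresholds$min_mapping_quality)
  L <- region$end - region$start
  pos <- region$start + seq_len(L) - 1L
  ref_chars <- strsplit(substr(reference[[contig]], region$start + 1L,
                               region$end), "")[[1]]
  bases <- c("A", "C", "G", "T")
  base_long <- tibble(
    pos = rep(pos, each = 4L),
    allele = rep(bases, L),
    count = as.integer(res$counts)
  )
  base_long <- base_long[base_long$count > 0, , drop = FALSE]
  ind <- tibble(pos = res$indel_pos, allele = res$indel_allele,
                count = res$indel_count)
  site <- tibble(pos = pos, ref = ref_chars, depth = res$depth,
                 n_lowbq = res$lowbq, n_lowmq = res$lowmq)
  out <- bind_rows(base_long, ind)
  out <- left_join(out, site, by = "pos")
  # keep zero-depth positions visible
  gaps <- site[site$depth == 0, , drop = FALSE]
  if (nrow(gaps)) {
    gaps$allele <- NA_character_
    gaps$count <- 0L
    out <- bind_rows(out, gaps)
  }
  out$contig <- contig
  out$is_ref <- !is.na(out$allele) & out$allele == out$ref
  out <- out[order(out$pos, -out$count), ]
  out[, c("contig", "pos", "ref", "depth", "n_lowbq", "n_lowmq",
          "allele", "count", "is_ref")]
}

# anchored (ref, alt) representation of a pileup allele key
allele_to_ref_alt <- function(allele, ref_base, pos, reference_seq) {
  n <- length(allele)
  ref <- ref_base
  alt <- allele
  del <- startsWith(allele, "-")
  ins <- startsWith(allele, "+")
  if (any(del)) {
    L <- as.integer(substring(allele[del], 2))
    ref[del] <- substring(reference_seq, pos[del] + 1L, pos[del] + 1L + L)
    alt[del] <- ref_base[del]
  }
  if (any(ins)) {
    alt[ins] <- paste0(ref_base[ins], substring(allele[ins], 2))
  }
  list(ref = ref, alt = alt)
}

#' Call variants from a pileup
#'
#' Applies the tiered allele-fraction rules to every site of a pileup.
#' In the first step only standard-tier calls (alt fraction >= 20%) are
#' emitted; in the second step, sites inside the duplicated region are
#' additionally screened at the relaxed threshold (>= 8%) and such calls
#' are tagged `relaxed-candidate`. Zygosity is `hom` iff the fraction
#' reaches the homozygous threshold, else `het`. Sites below `min_depth`
#' are skipped and reported in the `uncovered` attribute.
#'
#' @param pileup Long pileup tibble from [build_pileup()].
#' @param thresholds A [calling_thresholds()].
#' @param duplicated_intervals Interval tibble of the duplicated region
#'   (needed for `step = "second"`).
#' @param step `"first"` or `"second"`.
#' @param reference Optional named reference (to spell out deletion
#'   alleles); defaults to reconstructing from the pileup refs.
#' @return A calls tibble: `contig`, `pos`, `ref`, `alt`, `type`,
#'   `alt_count`, `depth`, `alt_fraction`, `zygosity`, `tier`. Attribute
#'   `uncovered` lists skipped shallow sites with a reason.
#' @export
call_variants <- function(pileup, thresholds = calling_thresholds(),
                          duplicated_intervals = NULL,
                          step = c("first", "second"), reference = NULL) {
  step <- match.arg(step)
  if (inherits(reference, "locus_model")) reference <- locus_reference(reference)
  site <- pileup[!duplicated(pileup$pos), c("contig", "pos", "depth")]
  uncovered <- site[site$depth < thresholds$min_depth, , drop = FALSE]
  if (nrow(uncovered)) uncovered$reason <- "below-min-depth"

  x <- pileup[!is.na(pileup$allele) & !pileup$is_ref &
                pileup$depth >= thresholds$min_depth, , drop = FALSE]
  x$alt_fraction <- x$count / x$depth
  in_dup <- if (is.null(duplicated_intervals)) rep(FALSE, nrow(x)) else {
    pos_in_intervals(x$pos, duplicated_intervals, contig = unique(x$contig))
  }
  thr <- ifelse(step == "second" & in_dup,
                thresholds$relaxed_alt_fraction,
                thresholds$standard_alt_fraction)
  x <- x[x$alt_fraction >= thr, , drop = FALSE]
  if (nrow(x) == 0) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(), alt_count = integer(),
                  depth = integer(), alt_fraction = double(),
                  zygosity = character(), tier = character())
    attr(out, "uncovered") <- uncovered
    return(out)
  }
  ref_seq <- if (!is.null(reference)) reference[[unique(x$contig)[1]]] else NULL
  if (is.null(ref_seq)) {
    # reconstruct reference context from the pileup itself; positions the
    # pileup does not cover are spelled N (only affects deletion alleles
    # running off the piled-up region)
    sm <- pileup[!duplicated(pileup$pos), c("pos", "ref")]
    sm <- sm[order(sm$pos), ]
    span <- max(sm$pos) - min(sm$pos) + 1L
    chars <- rep("N", span)
    chars[sm$pos - min(sm$pos) + 1L] <- sm$ref
    ra <- allele_to_ref_alt(x$allele, x$ref, x$pos - min(sm$pos),
                            paste(chars, collapse = ""))
  } else {
    ra <- allele_to_ref_alt(x$allele, x$ref, x$pos, ref_seq)
  }
  out <- tibble(
    contig = x$contig, pos = x$pos, ref = ra$ref, alt = ra$alt,
    type = ifelse(startsWith(x$allele, "-"), "del",
                  ifelse(startsWith(x$allele, "+"), "ins", "SNV")),
    alt_count = x$count, depth = x$depth, alt_fraction = x$alt_fraction,
    zygosity = ifelse(x$alt_fraction >= thresholds$hom_fraction, "hom", "het"),
    tier = ifelse(x$alt_fraction >= thresholds$standard_alt_fraction,
                  "standard", "relaxed-candidate")
  )
  out <- out[order(out$pos, desc(out$alt_count)), ]
  attr(out, "uncovered") <- uncovered
  out
}

#' Call a single pileup site
#'
#' Single-site convenience wrapper around the tiered rules, mirroring the
#' per-site decision table: standard-tier call at >= 20%, additional
#' relaxed-candidate call at >= 8% only in the second step and only inside
#' the duplicated region, homozygous at >= 85%.
#'
#' @param site Pileup rows for one position.
#' @inheritParams call_variants
#' @param in_duplicated_region Logical flag for the site.
#' @return A calls tibble with 0 or more rows (see [call_variants()]).
#' @export
call_site <- function(site, thresholds = calling_thresholds(),
                      in_duplicated_region = FALSE,
                      step = c("first", "second")) {
  step <- match.arg(step)
  stopifnot(length(unique(site$pos)) == 1)
  dup <- if (in_duplicated_region) {
    intervals(site$contig[1], site$pos[1], site$pos[1] + 1L)
  } else NULL
  call_variants(site, thresholds, duplicated_intervals = dup, step = step)
}

#' Two-step screen of a pileup
#'
#' First-step calling at the standard threshold everywhere, then a
#' second-step screen of the duplicated region at the relaxed threshold.
#' The standard set is invariant under relaxation (threshold nesting), and
#' relaxed candidates are flagged for orthogonal confirmation. By default
#' the second step is only run when the first step yields no call, the
#' screening strategy for mutation-negative samples; `always_screen`
#' forces both for research use.
#'
#' @param pileup Long pileup tibble.
#' @param duplicated_intervals Interval tibble of the duplicated region.
#' @param thresholds A [calling_thresholds()].
#' @param always_screen Run the second step regardless of first-step
#'   results.
#' @return List with `standard` (first-step calls) and `relaxed_candidates`
#'   (second-step-only calls, possibly empty), both coordinate-sorted.
#' @export
two_step_screen <- function(pileup, duplicated_intervals,
                            thresholds = calling_thresholds(),
                            always_screen = FALSE) {
  standard <- call_variants(pileup, thresholds, duplicated_intervals,
                            step = "first")
  relaxed <- if (always_screen || nrow(standard) == 0) {
    both <- call_variants(pileup, thresholds, duplicated_intervals,
                          step = "second")
    anti_join(both, standard, by = c("contig", "pos", "ref", "alt"))
  } else {
    standard[0, ]
  }
  list(standard = standard, relaxed_candidates = relaxed)
}

#' Detect critical sites
#'
#' A truth site is critical when competitive mapping with the pseudogenes
#' leaves it detected below the standard threshold, or called with a
#' zygosity different from truth. Such sites define the empirical
#' critical-exon list that the CNV filter ledger excludes. Truth sites
#' with no usable pileup are reported as uncovered.
#'
#' @param truth A `truth_set`.
#' @param calls Calls tibble (both tiers).
#' @param pileup Long pileup tibble covering the truth sites.
#' @param thresholds A [calling_thresholds()].
#' @param expected_fraction Named vector of expected alt fractions by
#'   zygosity.
#' @param reference_seq Optional reference sequence; enables
#'   left-normalised matching of indel alleles.
#' @return Tibble of critical sites: `pos`, `ref`, `alt`, `zygosity`,
#'   `expected_fraction`, `observed_fraction`, `reason`
#'   (`below-threshold` / `zygosity-mismatch` / `uncovered`).
#' @export
detect_critical_sites <- function(truth, calls, pileup,
                                  thresholds = calling_thresholds(),
                                  expected_fraction = c(het = 0.5, hom = 1),
                                  reference_seq = NULL) {
  obs <- observed_alt_fractions(truth, pileup, reference_seq)
  norm_truth <- if (is.null(reference_seq)) truth else
    left_normalize(truth, reference_seq)
  norm_calls <- if (is.null(reference_seq) || nrow(calls) == 0) calls else
    left_normalize(calls, reference_seq)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    fr <- obs$observed_fraction[i]
    depth <- obs$depth[i]
    reason <- NA_character_
    if (is.na(depth) || depth < thresholds$min_depth) {
      reason <- "uncovered"
    } else if (fr < thresholds$standard_alt_fraction) {
      reason <- "below-threshold"
    } else {
      called <- norm_calls[norm_calls$pos == norm_truth$pos[i] &
                             norm_calls$alt == norm_truth$alt[i], ]
      if (nrow(called) > 0 && !any(called$zygosity == truth$zygosity[i])) {
        reason <- "zygosity-mismatch"
      }
    }
    if (!is.na(reason)) {
      out[[i]] <- tibble(
        pos = truth$pos[i], ref = truth$ref[i], alt = truth$alt[i],
        zygosity = truth$zygosity[i],
        expected_fraction = unname(expected_fraction[truth$zygosity[i]]),
        observed_fraction = fr, depth = depth, reason = reason)
    }
  }
  found <- bind_rows(out)
  if (nrow(found) == 0) {
    found <- tibble(pos = integer(), ref = character(), alt = character(),
                    zygosity = character(), expected_fraction = double(),
                    observed_fraction = double(), depth = integer(),
                    reason = character())
  }
  found
}

# observed alt fraction of each truth allele in a pileup; indel alleles are
# matched through their left-normalised representation when the reference
# is supplied (the pileup anchors indels where the aligner placed the gap)
observed_alt_fractions <- function(truth, pileup, reference_seq = NULL) {
  key <- truth_allele_key(truth)
  depth <- pileup$depth[match(truth$pos, pileup$pos)]
  cnt <- integer(nrow(truth))
  norm_truth <- if (is.null(reference_seq)) truth else
    left_normalize(truth, reference_seq)
  ind <- pileup[!is.na(pileup$allele) &
                  grepl("^[+-]", pileup$allele), , drop = FALSE]
  ind_key <- character(0)
  if (nrow(ind) > 0 && !is.null(reference_seq)) {
    ra <- allele_to_ref_alt(ind$allele, ind$ref, ind$pos, reference_seq)
    ind_norm <- left_normalize(tibble(pos = ind$pos, ref = ra$ref,
                                      alt = ra$alt), reference_seq)
    ind_key <- paste(ind_norm$pos, ind_norm$ref, ind_norm$alt)
  }
  for (i in seq_len(nrow(truth))) {
    if (truth$type[i] == "SNV" || is.null(reference_seq)) {
      rows <- pileup[pileup$pos == truth$pos[i] & !is.na(pileup$allele) &
                       pileup$allele == key[i], , drop = FALSE]
      cnt[i] <- if (nrow(rows)) rows$count[1] else 0L
    } else {
      hit <- which(ind_key == paste(norm_truth$pos[i], norm_truth$ref[i],
                                    norm_truth$alt[i]))
      if (length(hit)) {
        cnt[i] <- ind$count[hit[1]]
        depth[i] <- ind$depth[hit[1]]
      }
    }
  }
  tibble(pos = truth$pos, depth = depth,
         observed_count = cnt,
         observed_fraction = ifelse(is.na(depth) | depth == 0, NA_real_,
                                    cnt / depth))
}

# pileup allele key ("A", "-2", "+GT") of an anchored truth variant
truth_allele_key <- function(truth) {
  ifelse(truth$type == "SNV", truth$alt,
         ifelse(truth$type == "del",
                paste0("-", nchar(truth$ref) - nchar(truth$alt)),
                paste0("+", substring(truth$alt, 2))))
}

#' Filter calls against a population allele-frequency table
#'
#' Calls whose minor allele frequency in the table exceeds `max_af` are
#' removed (common polymorphisms); calls absent from the table are
#' retained.
#'
#' @param calls Calls tibble.
#' @param af_table Tibble with `contig`, `pos`, `ref`, `alt`, `af` (see
#'   [read_af_table()]).
#' @param max_af Maximum allele frequency to keep.
#' @return Filtered calls tibble.
#' @export
filter_common_variants <- function(calls, af_table, max_af = 0.01) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "af") %in% names(af_table)))
  m <- left_join(calls, af_table[, c("contig", "pos", "ref", "alt", "af")],
                 by = c("contig", "pos", "ref", "alt"))
  m <- m[is.na(m$af) | m$af <= max_af, , drop = FALSE]
  m$af <- NULL
  m
}

#' Read a tab-delimited allele-frequency table
#'
#' Columns: contig, pos (1-based in the file), ref, alt, af.
#' @param path File path.
#' @return Tibble with 0-based `pos`.
#' @export
read_af_table <- function(path) {
  x <- readr::read_tsv(path, col_names = c("contig", "pos", "ref", "alt", "af"),
                       col_types = "ciccd")
  if (any(is.na(x$pos)) || any(is.na(x$af))) {
    stop("malformed allele-frequency table row", call. = FALSE)
  }
  x$pos <- x$pos - 1L
  x
}

#' Write calls as a minimal VCF
#'
#' Emits tier and alt fraction in INFO and zygosity as GT.
#' @param calls Calls tibble.
#' @param path Output path.
#' @param contig_length Optional contig length for the header.
#' @return Invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path, contig_length = NA) {
  contig <- if (nrow(calls)) calls$contig[1] else "master"
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s%s>", contig,
            if (is.na(contig_length)) "" else sprintf(",length=%d", contig_length)),
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Detection tier\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt read fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"
  )
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTIER=%s;AF=%.4f;DP=%d\tGT\t%s",
                  calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                  calls$tier, calls$alt_fraction, calls$depth,
                  ifelse(calls$zygosity == "hom", "1/1", "0/1"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
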