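#' Parameters for a synthetic master-gene/pseudogene locus
#'
#' The defaults emulate the PKD1/PKD1P1-P6 situation: a master gene whose
#' 5' portion (exons 1-33) is segmentally duplicated into six pseudogene
#' copies at roughly 97.7% sequence identity, so that short reads from the
#' copies compete with reads from the genuine gene during mapping.
#'
#' @param exon_count Number of exons in the master gene.
#' @param exon_length Exon length in bases (exons are evenly sized and
#'   spaced; real exon-size heterogeneity is not modelled).
#' @param intron_length Intron length in bases, also used as the 5' and 3'
#'   flank.
#' @param master_length Total master length; defaults to
#'   `intron_length + exon_count * (exon_length + intron_length)`.
#' @param duplicated_exon_range Integer length-2 vector: first and last exon
#'   index (1-based) of the segmentally duplicated block.
#' @param n_pseudogenes Number of pseudogene copies.
#' @param identity Expected per-base sequence identity of each copy to the
#'   master, in (0, 1].
#' @param substitution_indel_ratio Fraction of divergence events that are
#'   substitutions (the remainder are 1-bp insertions/deletions). The
#'   default 1 keeps master/copy coordinates aligned.
#' @param seed Integer seed; every generator in this package is
#'   deterministic given its seed.
#' @return A `locus_params` list.
#' @export
locus_params <- function(exon_count = 33L, exon_length = 150L,
                         intron_length = 100L, master_length = NULL,
                         duplicated_exon_range = c(1L, min(33L, exon_count)),
                         n_pseudogenes = 6L, identity = 0.977,
                         substitution_indel_ratio = 1,
                         seed = 1L) {
  exon_count <- as.integer(exon_count)
  if (is.null(master_length)) {
    master_length <- intron_length + exon_count * (exon_length + intron_length)
  }
  if (exon_count * (exon_length + intron_length) > master_length) {
    stop("master_length too small for ", exon_count, " exons of ",
         exon_length, " bp with ", intron_length, " bp introns", call. = FALSE)
  }
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]", call. = FALSE)
  if (n_pseudogenes < 0) stop("n_pseudogenes must be >= 0", call. = FALSE)
  dr <- as.integer(duplicated_exon_range)
  if (length(dr) != 2 || dr[1] < 1 || dr[2] > exon_count || dr[1] > dr[2]) {
    stop("duplicated_exon_range must lie within [1, exon_count]", call. = FALSE)
  }
  structure(list(
    exon_count = exon_count, exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    master_length = as.integer(master_length),
    duplicated_exon_range = dr, n_pseudogenes = as.integer(n_pseudogenes),
    identity = identity, substitution_indel_ratio = substitution_indel_ratio,
    seed = as.integer(seed)
  ), class = "locus_params")
}

#' Generate the master locus
#'
#' Draws a uniform-random master sequence and lays out evenly spaced exons:
#' a 5' flank of `intron_length`, then alternating exons and introns. The
#' duplicated interval spans the duplicated exon block plus half an intron
#' on each side, modelling a segmental duplication that carries flanking
#' intronic sequence along with the exons.
#'
#' @param params A [locus_params()] object.
#' @return A `locus_model` list with elements `master` (sequence), `exons`,
#'   `duplicated` (interval tibbles), `pseudogenes` (empty until
#'   [derive_pseudogenes()] is called), `divergence`, and `params`.
#' @export
generate_master_locus <- function(params = locus_params()) {
  stopifnot(inherits(params, "locus_params"))
  with_seed_if(params$seed, {
    master <- random_dna(params$master_length)
    starts <- params$intron_length +
      (seq_len(params$exon_count) - 1L) * (params$exon_length + params$intron_length)
    exons <- intervals("master", starts, starts + params$exon_length,
                       name = paste0("exon", seq_len(params$exon_count)))
    exons$exon <- seq_len(params$exon_count)
    dr <- params$duplicated_exon_range
    pad <- params$intron_length %/% 2L
    dup <- intervals("master",
                     max(0L, exons$start[dr[1]] - pad),
                     min(params$master_length, exons$end[dr[2]] + pad))
    structure(list(
      master = master,
      exons = exons,
      duplicated = dup,
      pseudogenes = tibble(copy = integer(), name = character(), sequence = character()),
      divergence = tibble(copy = integer(), master_pos = integer(),
                          master_base = character(), copy_base = character()),
      params = params
    ), class = "locus_model")
  })
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model> master:", nchar(x$master), "bp,",
      nrow(x$exons), "exons,", nrow(x$pseudogenes), "pseudogene copies\n")
  cat("  duplicated interval:", x$duplicated$start, "-", x$duplicated$end, "\n")
  invisible(x)
}

#' Derive pseudogene copies of the duplicated region
#'
#' Each copy is the duplicated-interval sequence mutated independently so
#' that the expected per-base identity equals `params$identity`. Divergence
#' events are substitutions (and, when `substitution_indel_ratio < 1`,
#' 1-bp indels); every event is recorded in `locus$divergence` with its
#' master coordinate, so truth variants can later be planted to match or
#' avoid pseudogene alleles.
#'
#' @param locus A `locus_model` from [generate_master_locus()].
#' @param params Optional override of `locus$params`.
#' @param seed Seed for the divergence draw (default derives from the locus
#'   seed so the whole construction is reproducible).
#' @return The locus with `pseudogenes` and `divergence` filled in.
#' @export
derive_pseudogenes <- function(locus, params = locus$params,
                               seed = params$seed + 1L) {
  stopifnot(inherits(locus, "locus_model"))
  if (params$identity <= 0 || params$identity > 1) {
    stop("identity must be in (0, 1]", call. = FALSE)
  }
  dup <- locus$duplicated
  if (nrow(dup) == 0 || sum(dup$end - dup$start) == 0) {
    stop("duplicated interval is empty", call. = FALSE)
  }
  tmpl <- substr(locus$master, dup$start + 1L, dup$end)
  tmpl_chars <- strsplit(tmpl, "")[[1]]
  n <- length(tmpl_chars)
  with_seed_if(seed, {
    copies <- vector("list", params$n_pseudogenes)
    divs <- vector("list", params$n_pseudogenes)
    for (k in seq_len(params$n_pseudogenes)) {
      hit <- which(runif(n) < (1 - params$identity))
      is_sub <- runif(length(hit)) < params$substitution_indel_ratio
      chars <- tmpl_chars
      copy_base <- character(length(hit))
      if (any(is_sub)) {
        copy_base[is_sub] <- other_base(tmpl_chars[hit[is_sub]])
        chars[hit[is_sub]] <- copy_base[is_sub]
      }
      if (any(!is_sub)) {
        # 1-bp copy indels: deletion drops the base, insertion doubles it
        # with a random extra base appended after the master base
        idx <- hit[!is_sub]
        is_del <- runif(length(idx)) < 0.5
        chars[idx[is_del]] <- ""
        ins_extra <- sample(c("A", "C", "G", "T"), sum(!is_del), replace = TRUE)
        chars[idx[!is_del]] <- paste0(tmpl_chars[idx[!is_del]], ins_extra)
        copy_base[!is_sub][is_del] <- ""
        copy_base[!is_sub][!is_del] <- chars[idx[!is_del]]
      }
      copies[[k]] <- paste(chars, collapse = "")
      divs[[k]] <- tibble(
        copy = k,
        master_pos = dup$start + hit - 1L,
        master_base = tmpl_chars[hit],
        copy_base = copy_base
      )
    }
    locus$pseudogenes <- tibble(
      copy = seq_len(params$n_pseudogenes),
      name = paste0("pseudo", seq_len(params$n_pseudogenes)),
      sequence = vapply(copies, identity, character(1))
    )
    locus$divergence <- bind_rows(divs)
  })
  locus$params <- params
  locus
}

#' Plant truth variants on the master gene
#'
#' Builds the gold-standard truth set that downstream read simulation and
#' evaluation work against. Two density modes are supported: `"per-100bp"`
#' plants at least one variant in every 100 bp window of eligible coding
#' sequence (with additional variants drawn at `mutation_rate`), and
#' `"rate"` plants each eligible base independently with probability
#' `mutation_rate`. Pseudogene copies are never mutated.
#'
#' @param locus A `locus_model`.
#' @param density_mode `"per-100bp"` or `"rate"`.
#' @param mutation_rate Per-base variant probability.
#' @param zygosity_policy `"het"`, `"hom"`, or `"random"` (het is the
#'   hardest detection case and the default).
#' @param indel_fraction Fraction of planted variants that are indels.
#' @param indel_ext_p Geometric extension probability for indel length
#'   (length `1 + rgeom(1 - indel_ext_p)`).
#' @param region `"duplicated-coding"` restricts planting to exonic bases
#'   inside the duplicated interval; `"coding"` uses all exons.
#' @param avoid_divergence_sites Exclude positions at which any pseudogene
#'   copy diverges from the master, so a random alternative allele can
#'   never coincide with a pseudogene allele.
#' @param min_spacing Minimum distance between planted variants. Adjacent
#'   variants (an indel touching an SNV) have no unique anchored
#'   representation, which would make truth matching ill-defined.
#' @param window Window size for `"per-100bp"` mode.
#' @param seed Seed (defaults derives from the locus seed).
#' @return A `truth_set` tibble: `pos` (0-based), `ref`, `alt`, `type`
#'   (`SNV`/`ins`/`del`), `zygosity`.
#' @export
plant_variants <- function(locus, density_mode = c("per-100bp", "rate"),
                           mutation_rate = 0.02,
                           zygosity_policy = c("het", "hom", "random"),
                           indel_fraction = 0.15, indel_ext_p = 0.3,
                           region = c("duplicated-coding", "coding"),
                           avoid_divergence_sites = TRUE,
                           min_spacing = 10L,
                           window = 100L,
                           seed = locus$params$seed + 2L) {
  density_mode <- match.arg(density_mode)
  zygosity_policy <- match.arg(zygosity_policy)
  region <- match.arg(region)
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  }
  if (nrow(locus$exons) == 0) stop("locus has no exons", call. = FALSE)

  exons <- locus$exons
  coding <- interval_positions(exons)
  if (region == "duplicated-coding") {
    coding <- coding[pos_in_intervals(coding, locus$duplicated)]
  }
  if (avoid_divergence_sites && nrow(locus$divergence) > 0) {
    eligible <- setdiff(coding, unique(locus$divergence$master_pos))
  } else {
    eligible <- coding
  }
  if (density_mode == "per-100bp" && length(coding) < window) {
    stop("eligible coding sequence shorter than one window", call. = FALSE)
  }

  with_seed_if(seed, {
    if (density_mode == "rate") {
      pos <- eligible[runif(length(eligible)) < mutation_rate]
    } else {
      # windows are taken along the run of coding bases so every 100 bp of
      # coding sequence receives at least one variant
      win_id <- (seq_along(coding) - 1L) %/% window
      pos <- integer()
      for (w in split(coding, win_id)) {
        elig <- setdiff(intersect(w, eligible),
                        unlist(lapply(pos, function(p)
                          seq(p - min_spacing + 1L, p + min_spacing - 1L))))
        if (length(elig) == 0) next
        k <- max(1L, rbinom(1L, length(w), mutation_rate))
        picked <- integer()
        for (p in elig[sample.int(length(elig))]) {
          if (length(picked) >= k) break
          if (all(abs(p - picked) >= min_spacing)) picked <- c(picked, p)
        }
        pos <- c(pos, picked)
      }
    }
    pos <- sort(unique(pos))
    if (min_spacing > 1L && length(pos) > 1L) {
      keep <- rep(TRUE, length(pos))
      last <- pos[1]
      for (i in 2:length(pos)) {
        if (pos[i] - last < min_spacing) keep[i] <- FALSE else last <- pos[i]
      }
      pos <- pos[keep]
    }
    n <- length(pos)
    if (n == 0) {
      empty <- tibble(pos = integer(), ref = character(), alt = character(),
                      type = character(), zygosity = character())
      return(new_truth_set(empty))
    }
    type <- ifelse(runif(n) < indel_fraction,
                   ifelse(runif(n) < 0.5, "ins", "del"), "SNV")
    len <- ifelse(type == "SNV", 0L, 1L + rgeom(n, 1 - indel_ext_p))
    master_n <- nchar(locus$master)

    ref <- alt <- character(n)
    keep <- rep(TRUE, n)
    prev_end <- -10L  # last reference base consumed, for conflict detection
    for (i in seq_len(n)) {
      p <- pos[i]
      if (type[i] == "SNV") {
        if (p <= prev_end) { keep[i] <- FALSE; next }
        ref[i] <- substr(locus$master, p + 1L, p + 1L)
        alt[i] <- other_base(ref[i])
        prev_end <- p
      } else if (type[i] == "ins") {
        if (p <= prev_end) { keep[i] <- FALSE; next }
        ref[i] <- substr(locus$master, p + 1L, p + 1L)
        alt[i] <- paste0(ref[i], random_dna(len[i]))
        prev_end <- p
      } else {
        if (p + len[i] >= master_n || p + len[i] > max(coding) ||
            p <= prev_end) { keep[i] <- FALSE; next }
        ref[i] <- substr(locus$master, p + 1L, p + 1L + len[i])
        alt[i] <- substr(ref[i], 1L, 1L)
        prev_end <- p + len[i]
      }
    }
    zyg <- switch(zygosity_policy,
                  het = rep("het", n),
                  hom = rep("hom", n),
                  random = sample(c("het", "hom"), n, replace = TRUE))
    out <- tibble(pos = pos, ref = ref, alt = alt, type = type,
                  zygosity = zyg)[keep, ]
    new_truth_set(out)
  })
}

#' Plant variants whose alternative allele matches a pseudogene
#'
#' Selects substitution divergence sites and plants a heterozygous SNV whose
#' alternative allele equals the pseudogene base at the homologous position.
#' Reads carrying such an allele are indistinguishable from pseudogene reads
#' around the site itself, reproducing the competitive-mapping depression of
#' the observed alternative-allele fraction that makes these sites critical.
#'
#' @param locus A `locus_model` with pseudogenes derived.
#' @param n Number of variants to plant.
#' @param copy Which pseudogene copy to match (default 1).
#' @param min_spacing Minimum distance between planted sites.
#' @param coding_only Restrict to exonic divergence sites.
#' @param prefer `"isolated"` ranks candidate sites by the distance to
#'   their nearest neighbouring divergence site of the same copy and
#'   plants at the most isolated ones first. Sites inside long local
#'   identity tracts are exactly where reads carrying the pseudogene
#'   allele align perfectly to the pseudogene and are lost to the master
#'   pileup — the geometry that defines a critical site — so uniform
#'   sampling (`"random"`) under-represents the effect this class exists
#'   to exhibit.
#' @param seed Seed.
#' @return A `truth_set` tibble (all het SNVs).
#' @export
plant_matched_variants <- function(locus, n = 20L, copy = 1L,
                                   min_spacing = 150L, coding_only = TRUE,
                                   prefer = c("isolated", "random"),
                                   seed = locus$params$seed + 3L) {
  prefer <- match.arg(prefer)
  div <- locus$divergence
  all_pos <- sort(div$master_pos[div$copy == copy])
  div <- div[div$copy == copy & nchar(div$copy_base) == 1, , drop = FALSE]
  if (coding_only) {
    div <- div[pos_in_intervals(div$master_pos, locus$exons), , drop = FALSE]
  }
  if (nrow(div) == 0) stop("no usable divergence sites for copy ", copy, call. = FALSE)
  with_seed_if(seed, {
    if (prefer == "isolated") {
      iso <- vapply(div$master_pos, function(p) {
        gaps <- abs(setdiff(all_pos, p) - p)
        if (length(gaps)) min(gaps) else Inf
      }, double(1))
      div <- div[order(-iso, runif(nrow(div))), ]
    } else {
      div <- div[sample(nrow(div)), ]
    }
    picked <- integer()
    for (i in seq_len(nrow(div))) {
      p <- div$master_pos[i]
      if (all(abs(p - picked) >= min_spacing)) picked <- c(picked, p)
      if (length(picked) >= n) break
    }
    sel <- div[match(sort(picked), div$master_pos), ]
    new_truth_set(tibble(pos = sel$master_pos, ref = sel$master_base,
                         alt = sel$copy_base, type = "SNV", zygosity = "het"))
  })
}

new_truth_set <- function(x) {
  class(x) <- c("truth_set", class(x))
  x
}

#' Check a truth set against its locus
#'
#' Asserts that every reference allele matches the master sequence.
#' @param truth A `truth_set`.
#' @param locus The `locus_model` it was planted on.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_truth_set <- function(truth, locus) {
  obs <- substring(locus$master, truth$pos + 1L, truth$pos + nchar(truth$ref))
  bad <- which(obs != truth$ref)
  if (length(bad)) {
    stop("truth ref mismatch at pos ", paste(truth$pos[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# on-disk representations

#' Write locus reference and annotation files
#'
#' Writes a combined FASTA (master plus pseudogene contigs), BED files for
#' exons and the duplicated interval, and the truth set as a minimal VCF.
#'
#' @param locus A `locus_model`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth_set` to write as `truth.vcf`.
#' @return Invisibly, a named list of the paths written.
#' @export
write_locus <- function(locus, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- locus_reference(locus)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  exon_bed <- file.path(dir, "exons.bed")
  write_bed(locus$exons, exon_bed)
  dup_bed <- file.path(dir, "duplicated.bed")
  write_bed(locus$duplicated, dup_bed)
  paths <- list(fasta = fa, exons = exon_bed, duplicated = dup_bed)
  if (!is.null(truth)) {
    paths$truth <- file.path(dir, "truth.vcf")
    write_truth_vcf(truth, paths$truth, contig = "master",
                    contig_length = nchar(locus$master))
  }
  invisible(paths)
}

#' Combined reference sequences of a locus
#'
#' @param locus A `locus_model`.
#' @return Named character vector: master then pseudogene contigs.
#' @export
locus_reference <- function(locus) {
  setNames(c(locus$master, locus$pseudogenes$sequence),
           c("master", locus$pseudogenes$name))
}

#' Read/write BED intervals
#'
#' Three (plus optional name) column BED, 0-based half-open, tab-separated.
#' @param x Interval tibble.
#' @param path File path.
#' @return `read_bed` returns an interval tibble; `write_bed` its path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("contig", "start", "end", "name"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_tibble(x)
}

# minimal VCF emission: CHROM/POS/REF/ALT with zygosity as a GT sample column
write_truth_vcf <- function(truth, path, contig = "master", contig_length = NA) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s%s>", contig,
            if (is.na(contig_length)) "" else sprintf(",length=%d", contig_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttruth"
  )
  gt <- ifelse(truth$zygosity == "hom", "1/1", "0/1")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                  contig, truth$pos + 1L, truth$ref, truth$alt, gt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a truth-set VCF written by [write_locus()]
#' @param path VCF path.
#' @return A `truth_set` tibble.
#' @export
read_truth_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  out <- tibble(
    pos = vapply(f, function(x) as.integer(x[2]), integer(1)) - 1L,
    ref = vapply(f, `[`, character(1), 4),
    alt = vapply(f, `[`, character(1), 5),
    zygosity = ifelse(vapply(f, `[`, character(1), 10) == "1/1", "hom", "het")
  )
  out$type <- ifelse(nchar(out$ref) == nchar(out$alt), "SNV",
                     ifelse(nchar(out$ref) > nchar(out$alt), "del", "ins"))
  new_truth_set(out[, c("pos", "ref", "alt", "type", "zygosity")])
}
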