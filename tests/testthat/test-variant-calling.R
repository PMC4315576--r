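test_that("pileup counts reads, alleles and conserves depth", {
  set.seed(21)
  ref <- c(ref = random_seq(300))
  base_at <- function(p) substr(ref[[1]], p + 1, p + 1)
  alt_at <- function(p) setdiff(c("A", "C", "G", "T"), base_at(p))[1]

  # 10 reads, all reference
  reads <- dplyr::bind_rows(lapply(1:10, function(i)
    aln_row(50, "100M", substr(ref[[1]], 51, 150), qname = paste0("r", i))))
  pil <- build_pileup(reads, ref, intervals("ref", 50, 150),
                      calling_thresholds(min_depth = 1))
  site <- pil[pil$pos == 100, ]
  expect_equal(unique(site$depth), 10L)
  expect_true(all(site$is_ref))
  expect_equal(sum(site$count), 10L)

  # 3 of 10 reads carry an SNV at position 100
  alt_seq <- substr(ref[[1]], 51, 150)
  substr(alt_seq, 51, 51) <- alt_at(100)
  reads2 <- dplyr::bind_rows(
    reads[1:7, ],
    dplyr::bind_rows(lapply(1:3, function(i)
      aln_row(50, "100M", alt_seq, qname = paste0("a", i)))))
  pil2 <- build_pileup(reads2, ref, intervals("ref", 50, 150),
                       calling_thresholds(min_depth = 1))
  site2 <- pil2[pil2$pos == 100, ]
  expect_equal(unique(site2$depth), 10L)
  expect_equal(site2$count[site2$allele == alt_at(100)], 3L)
  expect_equal(sum(site2$count), unique(site2$depth))

  # a 2 bp deletion is keyed "-2" at its anchor; conservation still holds
  del_seq <- paste0(substr(ref[[1]], 51, 120), substr(ref[[1]], 123, 152))
  reads3 <- dplyr::bind_rows(
    reads,
    aln_row(50, "70M2D30M", del_seq, qname = "d1"))
  pil3 <- build_pileup(reads3, ref, intervals("ref", 50, 155),
                       calling_thresholds(min_depth = 1))
  anchor <- pil3[pil3$pos == 119, ]
  expect_true("-2" %in% anchor$allele)
  expect_equal(anchor$count[anchor$allele == "-2"], 1L)
  expect_equal(sum(anchor$count), unique(anchor$depth))
  # inside the deleted run the deleted read contributes no depth
  expect_equal(unique(pil3$depth[pil3$pos == 121]), 10L)
})

test_that("pileup conservation holds across a simulated locus", {
  locus <- derive_pseudogenes(generate_master_locus(
    locus_params(exon_count = 4, n_pseudogenes = 1, seed = 22)))
  truth <- plant_variants(locus, seed = 22)
  pairs <- simulate_locus_reads(locus, truth,
                                read_sim_params(target_coverage = 60,
                                                seed = 22))
  idx <- build_kmer_index(locus)
  aln <- map_read_pairs(pairs, idx, seed = 22)
  pil <- build_pileup(aln, locus)
  by_pos <- dplyr::summarise(dplyr::group_by(pil, pos),
                             s = sum(count), d = depth[1], .groups = "drop")
  expect_true(all(by_pos$s == by_pos$d))
})

test_that("tiered thresholds: the per-site decision table", {
  th <- calling_thresholds()
  dup <- TRUE; nondup <- FALSE
  cs <- function(alt_count, in_dup, step) {
    site <- pileup_site(10, "A", "T", alt_count, 100)
    call_site(site, th, in_duplicated_region = in_dup, step = step)
  }
  # 20% anywhere, first step: standard het call
  r <- cs(20, nondup, "first")
  expect_equal(nrow(r), 1); expect_equal(r$tier, "standard")
  expect_equal(r$zygosity, "het")
  # 8% in the duplicated region, second step only: relaxed candidate
  expect_equal(nrow(cs(8, dup, "first")), 0)
  r2 <- cs(8, dup, "second")
  expect_equal(r2$tier, "relaxed-candidate")
  # 8% outside the duplicated region: never called
  expect_equal(nrow(cs(8, nondup, "second")), 0)
  # 85%: homozygous
  expect_equal(cs(85, nondup, "first")$zygosity, "hom")
  expect_equal(cs(84, nondup, "first")$zygosity, "het")
  # below both thresholds: no call either step
  expect_equal(nrow(cs(7, dup, "first")), 0)
  expect_equal(nrow(cs(7, dup, "second")), 0)
  # thresholds must nest
  expect_error(calling_thresholds(relaxed_alt_fraction = 0.3), "relaxed")
})

test_that("shallow sites are reported uncovered, not silently negative", {
  site <- pileup_site(5, "A", "T", 8, 15)  # depth below min_depth = 20
  r <- call_site(site, calling_thresholds(), FALSE, "first")
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "uncovered")$pos, 5L)
  expect_equal(attr(r, "uncovered")$reason, "below-min-depth")
})

test_that("two-step screen: nesting, bucketing and scope", {
  th <- calling_thresholds()
  dup <- intervals("master", 0, 1000)
  pil <- dplyr::bind_rows(
    pileup_site(10, "A", "T", 25, 100),
    pileup_site(20, "C", "G", 12, 100),
    pileup_site(30, "G", "A", 5, 100))
  r <- two_step_screen(pil, dup, th, always_screen = TRUE)
  expect_equal(r$standard$pos, 10L)
  expect_equal(r$relaxed_candidates$pos, 20L)
  # outside the duplicated region no candidates appear
  pil2 <- pil; pil2$pos <- pil2$pos + 5000L
  r2 <- two_step_screen(pil2, dup, th, always_screen = TRUE)
  expect_equal(r2$standard$pos, 5010L)
  expect_equal(nrow(r2$relaxed_candidates), 0)
  # monotonicity: the standard set is invariant under relaxation
  both <- call_variants(pil, th, dup, step = "second")
  expect_true(all(r$standard$pos %in% both$pos))
  lower <- calling_thresholds(relaxed_alt_fraction = 0.04)
  more <- call_variants(pil, lower, dup, step = "second")
  expect_true(all(both$pos %in% more$pos))
  # screening off: second step skipped when the first step found a call
  r3 <- two_step_screen(pil, dup, th, always_screen = FALSE)
  expect_equal(nrow(r3$relaxed_candidates), 0)
})

test_that("critical sites: depressed fraction and zygosity mismatch", {
  truth <- tibble::tibble(pos = c(10L, 20L, 30L),
                          ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                          type = "SNV", zygosity = "het")
  pil <- dplyr::bind_rows(
    pileup_site(10, "A", "T", 12, 100),   # observed 12%: below threshold
    pileup_site(20, "C", "G", 90, 100),   # observed 90%: called hom
    pileup_site(30, "G", "A", 45, 100))   # healthy het
  calls <- call_variants(pil, calling_thresholds())
  crit <- detect_critical_sites(truth, calls, pil)
  expect_equal(nrow(crit), 2)
  expect_equal(crit$reason[crit$pos == 10], "below-threshold")
  expect_equal(crit$reason[crit$pos == 20], "zygosity-mismatch")
  # a truth site with no usable pileup is a distinct reason
  truth2 <- dplyr::bind_rows(truth, tibble::tibble(
    pos = 99L, ref = "A", alt = "C", type = "SNV", zygosity = "het"))
  crit2 <- detect_critical_sites(truth2, calls, pil)
  expect_equal(crit2$reason[crit2$pos == 99], "uncovered")
})

test_that("population-frequency filtering", {
  calls <- tibble::tibble(contig = "m", pos = c(1L, 2L, 3L),
                          ref = "A", alt = "T", type = "SNV",
                          alt_count = 30L, depth = 100L, alt_fraction = 0.3,
                          zygosity = "het", tier = "standard")
  af <- tibble::tibble(contig = "m", pos = c(1L, 2L), ref = "A", alt = "T",
                       af = c(0.05, 0.005))
  kept <- filter_common_variants(calls, af, max_af = 0.01)
  expect_setequal(kept$pos, c(2L, 3L))  # common removed, rare + absent kept
  expect_equal(nrow(filter_common_variants(calls, af, max_af = 1.0)), 3)

  dir <- withr::local_tempdir()
  tab <- file.path(dir, "af.tsv")
  writeLines(c("m\t2\tA\tT\t0.05", "m\t3\tA\tT\t0.001"), tab)
  t2 <- read_af_table(tab)
  expect_equal(t2$pos, c(1L, 2L))  # 1-based file -> 0-based
  writeLines(c("m\tnot_a_number\tA\tT\tx"), tab)
  expect_error(suppressWarnings(read_af_table(tab)), "malformed")
})

test_that("calls VCF emission carries tier, fraction and zygosity", {
  calls <- tibble::tibble(contig = "master", pos = 99L, ref = "A", alt = "T",
                          type = "SNV", alt_count = 40L, depth = 100L,
                          alt_fraction = 0.4, zygosity = "het",
                          tier = "standard")
  vcf <- file.path(withr::local_tempdir(), "c.vcf")
  write_calls_vcf(calls, vcf, contig_length = 1000)
  ln <- readLines(vcf)
  row <- ln[!startsWith(ln, "#")]
  f <- strsplit(row, "\t")[[1]]
  expect_equal(f[2], "100")  # 1-based on disk
  expect_match(f[8], "TIER=standard")
  expect_match(f[8], "AF=0.4")
  expect_equal(f[10], "0/1")
})
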