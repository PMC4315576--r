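test_that("master locus layout: evenly spaced disjoint exons", {
  p <- locus_params(exon_count = 33, exon_length = 150, intron_length = 100,
                    seed = 1)
  locus <- generate_master_locus(p)
  ex <- locus$exons
  expect_equal(nrow(ex), 33)
  expect_true(all(ex$end - ex$start == 150))
  # disjoint and sorted
  expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  expect_equal(nchar(locus$master), p$master_length)
  # duplicated interval covers the duplicated exon block
  expect_lte(locus$duplicated$start, ex$start[1])
  expect_gte(locus$duplicated$end, ex$end[33])
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_master_locus(locus_params(seed = 7))
  b <- generate_master_locus(locus_params(seed = 7))
  expect_identical(a$master, b$master)
  d1 <- derive_pseudogenes(a)
  d2 <- derive_pseudogenes(b)
  expect_identical(d1$pseudogenes, d2$pseudogenes)
  expect_identical(d1$divergence, d2$divergence)
  c3 <- generate_master_locus(locus_params(seed = 8))
  expect_false(identical(a$master, c3$master))
})

test_that("GC content of a uniform-random master is near one half", {
  locus <- generate_master_locus(
    locus_params(exon_count = 10, exon_length = 150, intron_length = 100,
                 master_length = 100000, seed = 3))
  gc <- sum(strsplit(locus$master, "")[[1]] %in% c("G", "C")) / 100000
  # binomial expectation 0.5, sd ~ 0.0016; 0.01 is beyond 6 sigma
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("sizing and parameter validation errors", {
  expect_error(locus_params(exon_count = 100, exon_length = 150,
                            intron_length = 100, master_length = 1000),
               "too small")
  expect_error(locus_params(identity = 0), "identity")
  expect_error(locus_params(identity = 1.2), "identity")
  expect_error(locus_params(duplicated_exon_range = c(0, 10)),
               "duplicated_exon_range")
  expect_error(locus_params(duplicated_exon_range = c(1, 99)),
               "duplicated_exon_range")
})

test_that("identity = 1 copies the duplicated region exactly", {
  locus <- generate_master_locus(
    locus_params(exon_count = 5, n_pseudogenes = 1, identity = 1, seed = 2))
  locus <- derive_pseudogenes(locus)
  dup_seq <- substr(locus$master, locus$duplicated$start + 1,
                    locus$duplicated$end)
  expect_identical(locus$pseudogenes$sequence[1], dup_seq)
  expect_equal(nrow(locus$divergence), 0)
})

test_that("divergence event count follows the binomial oracle", {
  # 10 kb duplicated region at 97.7% identity: Binomial(10000, 0.023),
  # mean 230, sd ~ 15; assert within 3 sigma
  p <- locus_params(exon_count = 10, exon_length = 800, intron_length = 200,
                    duplicated_exon_range = c(1, 10), n_pseudogenes = 6,
                    identity = 0.977, seed = 11)
  locus <- derive_pseudogenes(generate_master_locus(p))
  dup_len <- locus$duplicated$end - locus$duplicated$start
  exp_n <- dup_len * 0.023
  sd_n <- sqrt(dup_len * 0.023 * 0.977)
  counts <- table(locus$divergence$copy)
  expect_length(counts, 6)
  for (k in 1:6) expect_lt(abs(counts[[k]] - exp_n), 3 * sd_n)
  # copies diverge independently: no two copies share all their sites
  sites <- split(locus$divergence$master_pos, locus$divergence$copy)
  expect_false(identical(sort(sites[[1]]), sort(sites[[2]])))
  # per-copy observed identity within a 99% binomial CI of the request
  for (k in 1:6) {
    phat <- 1 - counts[[k]] / dup_len
    ci <- 0.977 + c(-1, 1) * 2.576 * sqrt(0.023 * 0.977 / dup_len)
    expect_gte(phat, ci[1]); expect_lte(phat, ci[2])
  }
})

test_that("divergence sites fall inside the duplicated interval and are recorded", {
  locus <- derive_pseudogenes(generate_master_locus(locus_params(seed = 4)))
  div <- locus$divergence
  expect_true(all(div$master_pos >= locus$duplicated$start &
                    div$master_pos < locus$duplicated$end))
  # recorded master base matches the master sequence
  expect_identical(substring(locus$master, div$master_pos + 1,
                             div$master_pos + 1), div$master_base)
  # substitution-only default: copy base differs and is a single base
  expect_true(all(nchar(div$copy_base) == 1 & div$copy_base != div$master_base))
})

test_that("indel divergence changes copy length when enabled", {
  p <- locus_params(exon_count = 5, n_pseudogenes = 2, identity = 0.95,
                    substitution_indel_ratio = 0.5, seed = 6)
  locus <- derive_pseudogenes(generate_master_locus(p))
  dup_len <- locus$duplicated$end - locus$duplicated$start
  expect_true(any(nchar(locus$pseudogenes$sequence) != dup_len))
})

test_that("per-100bp planting density satisfies the pigeonhole bound", {
  p <- locus_params(exon_count = 22, exon_length = 150, intron_length = 100,
                    duplicated_exon_range = c(1, 22), n_pseudogenes = 0,
                    seed = 5)
  locus <- generate_master_locus(p)
  truth <- plant_variants(locus, density_mode = "per-100bp", seed = 5)
  # 3300 coding bases -> at least 33 variants
  expect_gte(nrow(truth), 33)
  # every 100 bp window of coding sequence holds a variant
  coding <- sort(unlist(Map(seq.int, locus$exons$start,
                            locus$exons$end - 1L)))
  win <- (seq_along(coding) - 1L) %/% 100L
  hit <- vapply(split(coding, win),
                function(w) any(truth$pos %in% w), logical(1))
  expect_true(all(hit))
})

test_that("zero-rate planting yields an empty truth set", {
  locus <- generate_master_locus(locus_params(exon_count = 5, seed = 1))
  truth <- plant_variants(locus, density_mode = "rate", mutation_rate = 0,
                          seed = 1)
  expect_equal(nrow(truth), 0)
})

test_that("rate-mode planting follows the binomial oracle", {
  # ~10 kb of coding sequence at rate 0.02: Binomial(n, 0.02)
  p <- locus_params(exon_count = 20, exon_length = 500, intron_length = 100,
                    duplicated_exon_range = c(1, 20), n_pseudogenes = 0,
                    seed = 9)
  locus <- generate_master_locus(p)
  truth <- plant_variants(locus, density_mode = "rate", mutation_rate = 0.02,
                          seed = 9)
  n <- 20 * 500
  expect_lt(abs(nrow(truth) - n * 0.02), 3 * sqrt(n * 0.02 * 0.98) + 5)
})

test_that("truth refs always match the master and stay inside exons", {
  locus <- derive_pseudogenes(generate_master_locus(locus_params(seed = 10)))
  truth <- plant_variants(locus, seed = 10)
  expect_true(validate_truth_set(truth, locus))
  in_exon <- vapply(truth$pos, function(p)
    any(p >= locus$exons$start & p < locus$exons$end), logical(1))
  expect_true(all(in_exon))
  # default zygosity policy: heterozygous
  expect_true(all(truth$zygosity == "het"))
  # mutation_rate outside [0,1) rejected
  expect_error(plant_variants(locus, mutation_rate = 1), "mutation_rate")
})

test_that("pseudogene-matching variants reproduce a pseudogene allele", {
  locus <- derive_pseudogenes(generate_master_locus(locus_params(seed = 12)))
  tm <- plant_matched_variants(locus, n = 10, copy = 1, seed = 12)
  div1 <- locus$divergence[locus$divergence$copy == 1, ]
  m <- match(tm$pos, div1$master_pos)
  expect_false(any(is.na(m)))
  expect_identical(tm$alt, div1$copy_base[m])
  expect_identical(tm$ref, div1$master_base[m])
})

test_that("locus files round-trip: FASTA, BED and truth VCF", {
  locus <- derive_pseudogenes(generate_master_locus(
    locus_params(exon_count = 4, n_pseudogenes = 2, seed = 3)))
  truth <- plant_variants(locus, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_locus(locus, dir, truth = truth)
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(length(fa), 3)
  expect_identical(as.character(fa[["master"]]), locus$master)
  bed <- read_bed(paths$exons)
  expect_equal(bed$start, locus$exons$start)
  expect_equal(bed$end, locus$exons$end)
  rt <- read_truth_vcf(paths$truth)
  expect_equal(rt$pos, truth$pos)
  expect_identical(rt$ref, truth$ref)
  expect_identical(rt$alt, truth$alt)
  expect_identical(rt$zygosity, truth$zygosity)
  # cross-check the emitted VCF with an independent parser
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(paths$truth, verbose = FALSE))
  expect_equal(as.integer(vcfR::getPOS(v)), truth$pos + 1L)
  expect_identical(vcfR::getREF(v), truth$ref)
  expect_identical(vcfR::getALT(v), truth$alt)
})
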