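test_that("the evaluation region is the exons dilated by the flank", {
  set.seed(41)
  ref <- random_seq(1000)
  exons <- intervals("master", 100, 200, name = "exon1")
  # truth at exon_end + 28: inside with flank 30, outside with flank 20
  tr <- tibble::tibble(pos = 227L, ref = substr(ref, 228, 228),
                       alt = "A", type = "SNV", zygosity = "het")
  tr$alt <- setdiff(c("A", "C", "G", "T"), tr$ref)[1]
  calls <- tibble::tibble(contig = "master", pos = 227L, ref = tr$ref,
                          alt = tr$alt, type = "SNV", alt_count = 50L,
                          depth = 100L, alt_fraction = 0.5,
                          zygosity = "het", tier = "standard")
  r30 <- compare_to_truth(calls, tr, exons, eval_params(flank = 30),
                          reference_seq = ref)
  expect_equal(r30$counts$TP, 1)
  r20 <- compare_to_truth(calls, tr, exons, eval_params(flank = 20),
                          reference_seq = ref)
  expect_equal(r20$counts$TP + r20$counts$FN, 0)  # excluded entirely
  expect_equal(r20$counts$FP, 0)
})

test_that("identical call and truth sets give perfect scores", {
  set.seed(42)
  ref <- random_seq(2000)
  exons <- intervals("master", c(100, 600), c(300, 800))
  pos <- c(150L, 250L, 700L)
  tr <- tibble::tibble(pos = pos,
                       ref = substring(ref, pos + 1, pos + 1),
                       alt = NA_character_, type = "SNV", zygosity = "het")
  tr$alt <- vapply(tr$ref, function(b) setdiff(c("A","C","G","T"), b)[1], "")
  calls <- tibble::tibble(contig = "master", pos = tr$pos, ref = tr$ref,
                          alt = tr$alt, type = "SNV", alt_count = 50L,
                          depth = 100L, alt_fraction = 0.5, zygosity = "het",
                          tier = "standard")
  r <- compare_to_truth(calls, tr, exons, reference_seq = ref)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$counts$FP, 0)
  expect_equal(r$specificity_per_site, 1)
  expect_equal(r$zygosity_concordance, 1)
})

test_that("indel matching is representation-independent via left-normalisation", {
  # reference with a homopolymer so the same deletion has two anchors
  ref <- paste0(random_seq(50), "GTTTTTC", random_seq(50))
  exons <- intervals("master", 40, 70)
  # truth anchored at the leftmost T (pos 51 0-based: G at 50)
  tr <- tibble::tibble(pos = 50L, ref = "GT", alt = "G", type = "del",
                       zygosity = "het")
  # call anchored mid-homopolymer: TT -> T at pos 53
  calls <- tibble::tibble(contig = "master", pos = 53L, ref = "TT", alt = "T",
                          type = "del", alt_count = 40L, depth = 100L,
                          alt_fraction = 0.4, zygosity = "het",
                          tier = "standard")
  r <- compare_to_truth(calls, tr, exons, reference_seq = ref)
  expect_equal(r$counts$TP, 1)
  expect_equal(r$counts$FP, 0)
})

test_that("near-miss calls are a discordance class, not true positives", {
  ref <- random_seq(500)
  exons <- intervals("master", 0, 400)
  tr <- tibble::tibble(pos = 100L, ref = substr(ref, 101, 101), alt = "T",
                       type = "SNV", zygosity = "het")
  tr$alt <- setdiff(c("A", "C", "G", "T"), tr$ref)[1]
  near <- tibble::tibble(contig = "master", pos = 101L,
                         ref = substr(ref, 102, 102), alt = "G",
                         type = "SNV", alt_count = 50L, depth = 100L,
                         alt_fraction = 0.5, zygosity = "het",
                         tier = "standard")
  near$alt <- setdiff(c("A", "C", "G", "T"), near$ref)[1]
  r <- compare_to_truth(near, tr, exons, reference_seq = ref)
  expect_equal(r$counts$TP, 0)
  expect_equal(r$per_variant$status, "near-miss")
})

test_that("a coordinate-system mismatch is detected via the ref allele", {
  ref <- random_seq(300)
  tr <- tibble::tibble(pos = 100L, ref = "X", alt = "A", type = "SNV",
                       zygosity = "het")
  expect_error(compare_to_truth(tr[0, ], tr, intervals("m", 0, 200),
                                reference_seq = ref),
               "coordinate systems differ")
})

test_that("sensitivity agrees with an exhaustive set-comparison oracle", {
  set.seed(43)
  ref <- random_seq(3000)
  exons <- intervals("master", 0, 3000)
  for (i in 1:100) {
    n_t <- sample(0:8, 1); n_extra <- sample(0:4, 1)
    tpos <- sort(sample(seq(10, 2900, by = 10), n_t))
    tr <- tibble::tibble(pos = as.integer(tpos),
                         ref = if (n_t) substring(ref, tpos + 1, tpos + 1)
                               else character(),
                         alt = rep(NA_character_, n_t),
                         type = rep("SNV", n_t),
                         zygosity = rep("het", n_t))
    tr$alt <- vapply(tr$ref, function(b) setdiff(c("A","C","G","T"), b)[1], "",
                     USE.NAMES = FALSE)
    called <- tr[sample(nrow(tr), sample(0:nrow(tr), 1)), , drop = FALSE]
    xpos <- sample(setdiff(seq(15, 2905, by = 10), tpos), n_extra)
    extra <- tibble::tibble(pos = as.integer(xpos),
                            ref = if (n_extra)
                              substring(ref, xpos + 1, xpos + 1)
                            else character(),
                            alt = rep(NA_character_, n_extra),
                            type = rep("SNV", n_extra),
                            zygosity = rep("het", n_extra))
    if (nrow(extra)) extra$alt <- vapply(extra$ref, function(b)
      setdiff(c("A","C","G","T"), b)[1], "", USE.NAMES = FALSE)
    calls <- dplyr::bind_rows(called, extra)
    calls$alt_count <- 50L; calls$depth <- 100L; calls$alt_fraction <- 0.5
    calls$tier <- "standard"; calls$contig <- "master"
    r <- compare_to_truth(calls, tr, exons, reference_seq = ref)
    o <- eval_oracle(paste(calls$pos, calls$alt), paste(tr$pos, tr$alt), 3000)
    expect_equal(r$counts$TP, o$tp)
    expect_equal(r$counts$FN, o$fn)
    expect_equal(r$counts$FP, o$fp)
  }
})

test_that("enlarging the flank never shrinks the evaluated truth", {
  set.seed(44)
  ref <- random_seq(2000)
  exons <- intervals("master", c(200, 900), c(400, 1100))
  pos <- sort(sample(100:1300, 30))
  tr <- tibble::tibble(pos = as.integer(pos),
                       ref = substring(ref, pos + 1, pos + 1),
                       alt = NA_character_, type = "SNV", zygosity = "het")
  tr$alt <- vapply(tr$ref, function(b) setdiff(c("A","C","G","T"), b)[1], "")
  empty <- tr[0, ]; empty$contig <- character(); empty$alt_fraction <- double()
  empty$tier <- character()
  n_prev <- -1
  for (fl in c(0, 10, 30, 60, 100)) {
    r <- compare_to_truth(empty, tr, exons, eval_params(flank = fl),
                          reference_seq = ref)
    n_eval <- r$counts$TP + r$counts$FN
    expect_gte(n_eval, n_prev)
    n_prev <- n_eval
  }
})

test_that("detection-rate table formats the printed validation rows", {
  tab <- detection_rate_table(tibble::tibble(
    category = c("verified", "distinct", "pathogenic", "ten"),
    total = c(683L, 160L, 63L, 10L),
    detected = c(681L, 159L, 62L, 10L)))
  expect_equal(tab$rate_percent, c(99.7, 99.4, 98.4, 100))
  expect_identical(tab$rate_label, c("99.7%", "99.4%", "98.4%", "100%"))
  expect_error(detection_rate_table(tibble::tibble(
    category = "x", total = 5L, detected = 6L)), "exceeds")
})

test_that("the validation experiment is deterministic from its seed", {
  cfg <- validation_config(
    locus = locus_params(exon_count = 4, duplicated_exon_range = c(1, 4),
                         n_pseudogenes = 1),
    reads = read_sim_params(target_coverage = 50),
    n_matched = 2, seed = 77)
  a <- run_validation_experiment(cfg)
  b <- run_validation_experiment(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(glance(a), glance(b))
  expect_identical(a$matched_sites, b$matched_sites)
})

test_that("easy discrimination at low identity yields full sensitivity", {
  cfg <- validation_config(
    locus = locus_params(exon_count = 4, duplicated_exon_range = c(1, 4),
                         n_pseudogenes = 2, identity = 0.5),
    reads = read_sim_params(target_coverage = 60),
    n_matched = 0, seed = 78)
  ex <- run_validation_experiment(cfg)
  expect_equal(ex$report$sensitivity, 1)
  expect_equal(ex$report$counts$FP, 0)
})

test_that("zero coverage degrades gracefully to an empty, valid report", {
  cfg <- validation_config(
    locus = locus_params(exon_count = 3, duplicated_exon_range = c(1, 3),
                         n_pseudogenes = 1),
    reads = read_sim_params(target_coverage = 0),
    n_matched = 0, seed = 79)
  ex <- run_validation_experiment(cfg)
  expect_equal(nrow(ex$calls), 0)
  expect_equal(ex$report$sensitivity, 0)
  expect_gt(ex$report$counts$FN, 0)
})

test_that("tidy and glance methods return the documented shapes", {
  cfg <- validation_config(
    locus = locus_params(exon_count = 3, duplicated_exon_range = c(1, 3),
                         n_pseudogenes = 1),
    reads = read_sim_params(target_coverage = 50),
    n_matched = 1, seed = 80)
  ex <- run_validation_experiment(cfg)
  td <- tidy(ex)
  expect_true(all(c("pos", "status", "class") %in% names(td)))
  gl <- glance(ex)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("sensitivity", "n_depressed_sites") %in% names(gl)))
  p <- autoplot(ex)
  expect_s3_class(p, "ggplot")
})
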