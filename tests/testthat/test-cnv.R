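test_that("target coverage matrix: uniform, empty and partial targets", {
  targets <- intervals("ref", c(0, 200, 400), c(100, 300, 500),
                       name = c("t1", "t2", "t3"))
  # 100 identical full-span reads give every covered target mean 100
  reads <- dplyr::bind_rows(lapply(1:100, function(i)
    aln_row(0, "300M", strrep("A", 300), qname = paste0("r", i))))
  cm <- target_coverage_matrix(list(s1 = reads), targets)
  expect_equal(cm$mean_depth[cm$name %in% c("t1", "t2")], c(100, 100))
  expect_equal(cm$mean_depth[cm$name == "t3"], 0)  # no reads there

  # half-covered target: base-weighted average against a direct oracle
  reads2 <- dplyr::bind_rows(lapply(1:10, function(i)
    aln_row(0, "50M", strrep("A", 50), qname = paste0("h", i))))
  cm2 <- target_coverage_matrix(list(s1 = reads2),
                                intervals("ref", 0, 100, name = "t"))
  cov <- c(rep(10, 50), rep(0, 50))
  expect_equal(cm2$mean_depth, mean(cov))
})

test_that("targets longer than the maximum segment size are split", {
  tg <- split_targets(intervals("ref", 0, 750, name = "big"), 300)
  expect_equal(nrow(tg), 3)
  expect_equal(tg$start, c(0L, 250L, 500L))
  expect_equal(tg$end, c(250L, 500L, 750L))
  expect_true(all(tg$end - tg$start <= 300))
  # short targets pass through unchanged
  expect_equal(nrow(split_targets(intervals("ref", 0, 150), 300)), 1)
})

test_that("normalisation and ratios: identity, deletion, scale invariance", {
  mk_cov <- function(depths, sample) {
    tibble::tibble(sample = sample, target_id = seq_along(depths),
                   name = paste0("t", seq_along(depths)), contig = "ref",
                   start = (seq_along(depths) - 1L) * 100L,
                   end = seq_along(depths) * 100L, mean_depth = depths)
  }
  base <- c(100, 100, 100, 100)
  cov <- dplyr::bind_rows(mk_cov(base, "idx"), mk_cov(base, "c1"))
  r <- normalize_and_ratio(cov, "idx", "c1")
  expect_equal(r$log2_ratio, rep(0, 4))

  # heterozygous single-target deletion: log2 close to -1
  del <- dplyr::bind_rows(mk_cov(c(100, 50, 100, 100), "idx"),
                          mk_cov(base, "c1"))
  r2 <- normalize_and_ratio(del, "idx", "c1")
  expect_lt(r2$log2_ratio[2], -0.8)
  expect_true(all(abs(r2$log2_ratio[-2]) < 0.2))

  # global x2 scaling disappears under internal normalisation
  scaled <- dplyr::bind_rows(mk_cov(base * 2, "idx"), mk_cov(base, "c1"))
  r3 <- normalize_and_ratio(scaled, "idx", "c1")
  expect_equal(r3$log2_ratio, rep(0, 4))

  # zero control depth flags the target low-coverage
  z <- dplyr::bind_rows(mk_cov(base, "idx"), mk_cov(c(100, 0, 100, 100), "c1"))
  r4 <- normalize_and_ratio(z, "idx", "c1")
  expect_true(r4$lowcov[2])
  expect_true(is.na(r4$log2_ratio[2]))
})

test_that("support bands: pass at >= 85%, indicated at 50-85%, none below", {
  mk_ratios <- function(l2_by_control) {
    dplyr::bind_rows(lapply(seq_along(l2_by_control), function(k)
      tibble::tibble(target_id = 1L, name = "t1", contig = "ref",
                     start = 0L, end = 100L, control = paste0("c", k),
                     log2_ratio = l2_by_control[k], lowcov = FALSE)))
  }
  p <- cnv_params()
  # deletion against 6/6 controls
  calls <- call_cnv(mk_ratios(rep(-1, 6)), p)
  expect_equal(calls$status, "pass")
  expect_equal(calls$direction, "del")
  expect_equal(calls$support_fraction, 1)
  # 4/6 controls (0.667): indicated
  calls2 <- call_cnv(mk_ratios(c(-1, -1, -1, -1, 0, 0)), p)
  expect_equal(calls2$status, "indicated")
  # magnitude below the log2 threshold: no call
  calls3 <- call_cnv(mk_ratios(rep(-0.5, 6)), p)
  expect_equal(nrow(calls3), 0)
  # panel size guards
  expect_error(call_cnv(mk_ratios(rep(-1, 2)), p), "at least 3")
  expect_warning(call_cnv(mk_ratios(rep(-1, 4)), p), "panel smaller")
})

test_that("adjacent passing targets merge into one event", {
  mk <- function(tid, l2) {
    dplyr::bind_rows(lapply(1:6, function(k)
      tibble::tibble(target_id = tid, name = paste0("t", tid), contig = "ref",
                     start = tid * 100L, end = tid * 100L + 50L,
                     control = paste0("c", k), log2_ratio = l2,
                     lowcov = FALSE)))
  }
  ratios <- dplyr::bind_rows(mk(1L, 0), mk(2L, -1), mk(3L, -1.1), mk(4L, 0))
  calls <- suppressWarnings(call_cnv(ratios, cnv_params()))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_targets, 2)
  expect_equal(calls$targets[[1]], c("t2", "t3"))
  expect_equal(calls$start, 200L)
  expect_equal(calls$end, 350L)
})

test_that("filter ledger names its reasons and is order-independent", {
  p <- cnv_params(
    critical_regions = intervals("ref", 100, 200, name = "critical-exon"),
    artifact_regions = intervals("ref", 500, 600, name = "artifact-exon"),
    lowcov_regions = intervals("ref", 900, 950, name = "lowcov-exon"))
  mk_call <- function(start, end) {
    tibble::tibble(contig = "ref", start = start, end = end,
                   targets = list("t"), n_targets = 1L, direction = "del",
                   median_log2 = -1, support_fraction = 1, status = "pass",
                   filter_reasons = list(character()))
  }
  calls <- dplyr::bind_rows(mk_call(150L, 180L), mk_call(520L, 580L),
                            mk_call(700L, 800L), mk_call(910L, 940L))
  het <- tibble::tibble(contig = "ref", pos = 750L, ref = "A", alt = "T",
                        type = "SNV", alt_count = 45L, depth = 100L,
                        alt_fraction = 0.45, zygosity = "het",
                        tier = "standard")
  out <- apply_filter_ledger(calls, p, het_variant_evidence = het)
  expect_equal(out$filter_reasons[[1]], "critical-region")
  expect_equal(out$filter_reasons[[2]], "artifact-region")
  expect_equal(out$filter_reasons[[3]], "het-evidence")
  expect_equal(out$filter_reasons[[4]], "lowcov-region")
  expect_true(all(out$status == "filtered"))

  # a clean pass deletion is untouched
  clean <- apply_filter_ledger(mk_call(300L, 400L), p,
                               het_variant_evidence = het)
  expect_equal(clean$status, "pass")
  expect_length(clean$filter_reasons[[1]], 0)

  # reasons are a set: a call overlapping two ledger classes carries both,
  # independent of any application order
  p2 <- cnv_params(critical_regions = intervals("ref", 100, 200),
                   artifact_regions = intervals("ref", 150, 250))
  both <- apply_filter_ledger(mk_call(150L, 180L), p2)
  expect_setequal(both$filter_reasons[[1]],
                  c("artifact-region", "critical-region"))
})

test_that("het evidence outside the band or tier does not filter", {
  p <- cnv_params()
  call <- tibble::tibble(contig = "ref", start = 0L, end = 100L,
                         targets = list("t"), n_targets = 1L,
                         direction = "del", median_log2 = -1,
                         support_fraction = 1, status = "pass",
                         filter_reasons = list(character()))
  ev <- function(fr, tier = "standard", zyg = "het") {
    tibble::tibble(contig = "ref", pos = 50L, ref = "A", alt = "T",
                   type = "SNV", alt_count = as.integer(fr * 100),
                   depth = 100L, alt_fraction = fr, zygosity = zyg,
                   tier = tier)
  }
  expect_equal(apply_filter_ledger(call, p, ev(0.45))$status, "filtered")
  expect_equal(apply_filter_ledger(call, p, ev(0.95, zyg = "hom"))$status,
               "pass")
  expect_equal(apply_filter_ledger(call, p,
                                   ev(0.10, "relaxed-candidate"))$status,
               "pass")
})

test_that("MLPA ratio rule: deletion strictly below 75%", {
  r <- mlpa_ratio(c(p1 = 0.5, p2 = 0.74, p3 = 0.75, p4 = 1.0),
                  c(p1 = 1, p2 = 1, p3 = 1, p4 = 1))
  expect_equal(r$deletion, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$ratio, c(0.5, 0.74, 0.75, 1.0))
  # zero control RPA: undefined, not a deletion
  r2 <- mlpa_ratio(c(p1 = 0.5), c(p1 = 0))
  expect_true(r2$undefined)
  expect_false(r2$deletion)
  expect_error(mlpa_ratio(c(a = 1), c(b = 1)), "probe sets")
})

test_that("coverage QC: uniform, empty and mixed-depth targets", {
  reads <- dplyr::bind_rows(lapply(1:100, function(i)
    aln_row(0, "100M", strrep("A", 100), qname = paste0("r", i))))
  qc <- coverage_qc(reads, intervals("ref", 0, 100, name = "t1"))
  expect_equal(qc$mean_depth, 100)
  expect_equal(qc$fraction_at_floor, 1)

  qc2 <- coverage_qc(reads[0, ], intervals("ref", 0, 100, name = "t1"))
  expect_equal(qc2$fraction_at_floor, 0)

  # half the bases at 10x, half at 30x with floor 20
  reads3 <- dplyr::bind_rows(
    lapply(1:10, function(i) aln_row(0, "100M", strrep("A", 100),
                                     qname = paste0("a", i))),
    lapply(1:20, function(i) aln_row(50, "50M", strrep("A", 50),
                                     qname = paste0("b", i))))
  qc3 <- coverage_qc(reads3, intervals("ref", 0, 100, name = "t1"), floor = 20)
  expect_equal(qc3$fraction_at_floor, 0.5)
})
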