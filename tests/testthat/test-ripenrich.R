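test_that("detection thresholds are spike-in medians per fraction", {
  ann <- tiny_annotation()
  sheet <- tiny_rip_sheet()
  m <- tiny_expression()
  m["spk1", "CL1_input"] <- 5
  m["spk2", "CL1_input"] <- 6
  m["spk3", "CL1_input"] <- 7
  thr <- detection_threshold(m, ann, sheet, "CL1")
  expect_equal(thr$input_threshold, 6)
  expect_equal(thr$ip_threshold, 3.5)  # all IP spike values equal

  # translation equivariance
  thr2 <- detection_threshold(m + 1, ann, sheet, "CL1")
  expect_equal(thr2$ip_threshold, thr$ip_threshold + 1)
  expect_equal(thr2$input_threshold, thr$input_threshold + 1)
})

test_that("detection threshold preconditions are enforced", {
  ann <- tiny_annotation()
  sheet <- tiny_rip_sheet()
  m <- tiny_expression()
  expect_error(detection_threshold(m[1:3, ], ann, sheet, "CL1"),
               ">= 3 spike-in")
  two_inputs <- sheet
  two_inputs$fraction[2] <- "input"
  expect_error(detection_threshold(m, ann, two_inputs, "CL1"),
               "multiple input arrays")
})

test_that("enrichment records carry replicate-median folds and conjunctive detection", {
  ann <- tiny_annotation()
  sheet <- tiny_rip_sheet()
  m <- tiny_expression(ps1_ip = 6, ps1_input = 4, ps2_ip = 5, ps2_input = 5)
  rec <- enrichment(m, ann, sheet, "CL1")
  expect_setequal(rec$probeset_id, c("ps1", "ps2"))  # spike-ins excluded
  expect_equal(rec$fold[rec$probeset_id == "ps1"], 4.0)   # 2^(6-4)
  expect_equal(rec$fold[rec$probeset_id == "ps2"], 1.0)
  expect_true(all(rec$detected))
  expect_false(any(rec$selected))
  # fold identity invariant
  expect_equal(rec$fold, 2^(rec$ip_median_log2 - rec$input_log2))

  # probeset above IP threshold but below input threshold: not detected
  m2 <- tiny_expression(ps1_ip = 6, ps1_input = 3.5)
  rec2 <- enrichment(m2, ann, sheet, "CL1")
  expect_false(rec2$detected[rec2$probeset_id == "ps1"])
  rec2_ip <- enrichment(m2, ann, sheet, "CL1", detect_in = "ip")
  expect_true(rec2_ip$detected[rec2_ip$probeset_id == "ps1"])
})

test_that("fold is invariant to a joint shift of one cell line's arrays", {
  ann <- tiny_annotation()
  sheet <- tiny_rip_sheet()
  m <- tiny_expression(ps1_ip = 6.7, ps1_input = 4.1)
  r1 <- enrichment(m, ann, sheet, "CL1")
  r2 <- enrichment(m + 2.5, ann, sheet, "CL1")
  expect_equal(r1$fold, r2$fold)
})

test_that("top-quantile selection matches the brute-force oracle", {
  rec <- data.frame(
    probeset_id = sprintf("ps%04d", 1:1000),
    cell_line = "CL1",
    ip_median_log2 = log2(1:1000), input_log2 = 0,
    fold = as.numeric(1:1000),
    detected = TRUE, selected = FALSE,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("enrichment_records", "data.frame")
  sel <- select_bound(rec, quantile_q = 0.995)
  expect_equal(sel$probeset_id[sel$selected], sprintf("ps%04d", 996:1000))
  expect_equal(sum(sel$selected), 5L)
  expect_equal(sel$selected,
               select_bound_oracle(rec$fold, rec$detected, 0.995))

  # randomised agreement with the oracle, including undetected records
  set.seed(33)
  for (i in 1:10) {
    rec$fold <- rexp(1000) + 0.01
    rec$detected <- runif(1000) > 0.2
    q <- runif(1, 0.9, 0.999)
    got <- select_bound(rec, q)
    expect_equal(got$selected,
                 select_bound_oracle(rec$fold, rec$detected, q))
    expect_true(all(got$detected[got$selected]))  # selected implies detected
    expect_lte(sum(got$selected), ceiling((1 - q) * 1000))
  }
})

test_that("selection boundary cases: ties and q = 0", {
  rec <- data.frame(
    probeset_id = paste0("ps", 1:8), cell_line = "CL1",
    ip_median_log2 = 1, input_log2 = 0,
    fold = rep(2, 8), detected = TRUE, selected = FALSE,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("enrichment_records", "data.frame")
  expect_equal(sum(select_bound(rec, 0.995)$selected), 0L)  # all tied

  rec$fold <- c(1, 2, 3, 4, 5, 6, 7, 8)
  rec$detected <- c(FALSE, rep(TRUE, 7))
  sel0 <- select_bound(rec, 0)
  expect_equal(sel0$probeset_id[sel0$selected], paste0("ps", 2:8))
  expect_error(select_bound(rec[0, ], 0.995), "empty record")
})

test_that("overlap classification partitions selections with both folds", {
  mk <- function(ids, sel, folds, cl) {
    rec <- data.frame(
      probeset_id = ids, cell_line = cl,
      ip_median_log2 = log2(folds), input_log2 = 0, fold = folds,
      detected = TRUE, selected = sel, stringsAsFactors = FALSE
    )
    class(rec) <- c("enrichment_records", "data.frame")
    rec
  }
  ids <- c("x", "y", "z", "w")
  a <- mk(ids, c(TRUE, TRUE, FALSE, FALSE), c(3.97, 5.0, 0.77, 1.1), "A")
  b <- mk(ids, c(FALSE, TRUE, TRUE, FALSE), c(2.61, 4.0, 8.19, 0.9), "B")
  tab <- classify_overlap(a, b)
  expect_equal(tab$stratum[tab$probeset_id == "y"], "both")
  expect_equal(tab$stratum[tab$probeset_id == "x"], "A_only")
  expect_equal(tab$stratum[tab$probeset_id == "z"], "B_only")
  expect_false("w" %in% tab$probeset_id)
  # both cell lines' folds reported even where not selected
  expect_equal(tab$fold_a[tab$probeset_id == "z"], 0.77)
  expect_equal(tab$fold_b[tab$probeset_id == "x"], 2.61)

  empty <- classify_overlap(mk(ids, rep(FALSE, 4), 1:4, "A"),
                            mk(ids, rep(FALSE, 4), 1:4, "B"))
  expect_equal(nrow(empty), 0L)
})

test_that("the report orders strata by the defining cell line's fold", {
  mk <- function(ids, sel, folds, cl) {
    rec <- data.frame(
      probeset_id = ids, cell_line = cl,
      ip_median_log2 = log2(folds), input_log2 = 0, fold = folds,
      detected = TRUE, selected = sel, stringsAsFactors = FALSE
    )
    class(rec) <- c("enrichment_records", "data.frame")
    rec
  }
  ids <- c("m1", "m2", "m3", "m4", "m5")
  a <- mk(ids, c(TRUE, TRUE, TRUE, TRUE, FALSE),
          c(2.44, 5.18, 3.97, 4.04, 1.2), "A")
  b <- mk(ids, c(TRUE, TRUE, TRUE, TRUE, TRUE),
          c(2.94, 5.81, 2.61, 2.61, 8.19), "B")
  ann <- suppressWarnings(probe_annotation(
    probe_id = ids[1:4], probeset_id = ids[1:4],
    rna_class = rep("mature_miRNA", 4)
  ))
  tab <- classify_overlap(a, b)
  rep_ <- suppressWarnings(enrichment_report(tab, ann))
  both <- rep_[rep_$stratum == "both", ]
  expect_equal(both$fold_a, sort(both$fold_a, decreasing = TRUE))
  expect_equal(both$probeset_id[1], "m2")  # 5.18 first
  bonly <- rep_[rep_$stratum == "B_only", ]
  expect_equal(bonly$probeset_id, "m5")
  expect_warning(enrichment_report(tab, ann), "unknown")
  expect_equal(rep_$rna_class[rep_$probeset_id == "m5"], "unknown")

  empty <- classify_overlap(a[0, ], b[0, ])
  expect_equal(nrow(enrichment_report(empty, ann)), 0L)
})

test_that("report sort is stable on tied folds", {
  mk <- function(ids, folds, cl) {
    rec <- data.frame(
      probeset_id = ids, cell_line = cl,
      ip_median_log2 = log2(folds), input_log2 = 0, fold = folds,
      detected = TRUE, selected = TRUE, stringsAsFactors = FALSE
    )
    class(rec) <- c("enrichment_records", "data.frame")
    rec
  }
  ids <- c("t1", "t2", "t3")
  ann <- suppressWarnings(probe_annotation(
    probe_id = ids, probeset_id = ids, rna_class = rep("snoRNA_CD", 3)))
  tab <- classify_overlap(mk(ids, c(2, 2, 2), "A"), mk(ids, c(1, 1, 1), "B"))
  rep_ <- enrichment_report(tab, ann)
  expect_equal(rep_$probeset_id, ids)  # input order kept on ties
})
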