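cfg_small <- function() assay_config(min_library_reads = 1000)

test_that("end-to-end pipeline recovers the three simulated truth classes", {
  model <- alk_exon_model()
  cfg <- cfg_small()
  fus <- simulate_and_classify("FUSION", model, cfg, seed = 101)
  expect_equal(fus$verdict, "FUSION_PREDICTED")
  expect_lt(fus$p_value, cfg$alpha)
  expect_gt(fus$tk_mean, fus$control_mean)
  wt <- simulate_and_classify("WILD_TYPE", model, cfg, seed = 102,
                              on_target = 300L, background = 1200L)
  expect_equal(wt$verdict, "WILD_TYPE_EXPRESSION")
  expect_gte(wt$p_value, cfg$alpha)
  sil <- simulate_and_classify("SILENT", model, cfg, seed = 103)
  expect_equal(sil$verdict, "NOT_EXPRESSED")
  expect_equal(sil$p_value, 1)
  expect_true("LOW_COVERAGE_UNRELIABLE" %in% sil$flags)
})

test_that("run_sample writes coverage, result and JSON artifacts deterministically", {
  model <- alk_exon_model()
  cfg <- cfg_small()
  prof <- sim_profile("FUSION", model, on_target_reads = 150L,
                      background_reads = 1350L, seed = 104L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  out <- file.path(tempfile(), "reports")
  rep1 <- run_sample(sam, model, cfg, sample_id = "S1", out_dir = out)
  expect_s3_class(rep1, "sample_report")
  for (suffix in c(".coverage.tsv", ".coverage.json", ".result.tsv",
                   ".result.json")) {
    expect_true(file.exists(file.path(out, paste0("S1", suffix))))
  }
  js <- jsonlite::read_json(file.path(out, "S1.result.json"))
  expect_equal(js$verdict, "FUSION_PREDICTED")
  expect_equal(js$sample_id, "S1")
  expect_equal(js$n_control, 5)
  tsv <- utils::read.delim(file.path(out, "S1.result.tsv"))
  expect_equal(tsv$verdict, "FUSION_PREDICTED")
  expect_equal(tsv$p_value, round(rep1$result$p_value, 3))
  # rerunning the identical input reproduces the identical result artifacts
  out2 <- file.path(tempfile(), "reports2")
  run_sample(sam, model, cfg, sample_id = "S1", out_dir = out2)
  expect_identical(readLines(file.path(out, "S1.result.json")),
                   readLines(file.path(out2, "S1.result.json")))
  expect_identical(readLines(file.path(out, "S1.coverage.tsv")),
                   readLines(file.path(out2, "S1.coverage.tsv")))
})

test_that("batch_screen screens a manifest with per-sample error isolation", {
  model <- alk_exon_model()
  cfg <- cfg_small()
  dir <- tempfile(); dir.create(dir)
  mk <- function(kind, name, seed) {
    prof <- sim_profile(kind, model, on_target_reads = 150L,
                        background_reads = 1350L, seed = seed)
    sam <- file.path(dir, paste0(name, ".sam"))
    simulate_alignments(prof, sam, truth_path = NA)
    sam
  }
  manifest <- tibble::tibble(
    sample_id = c("fusion", "wildtype", "silent", "broken"),
    path = c(mk("FUSION", "f", 201), mk("WILD_TYPE", "w", 202),
             mk("SILENT", "s", 203), file.path(dir, "missing.sam"))
  )
  expect_warning(res <- batch_screen(manifest, model, cfg), "broken")
  expect_equal(nrow(res), 4)
  expect_equal(res$verdict[res$sample_id == "fusion"], "FUSION_PREDICTED")
  expect_equal(res$verdict[res$sample_id == "wildtype"],
               "WILD_TYPE_EXPRESSION")
  expect_equal(res$verdict[res$sample_id == "silent"], "NOT_EXPRESSED")
  expect_equal(res$verdict[res$sample_id == "broken"], "ERROR")
  expect_true(is.na(res$p_value[res$sample_id == "broken"]))
  # the same three good samples under the published 2.5M-read floor all QC-fail
  res_qc <- batch_screen(manifest[1:3, ], model, assay_config())
  expect_true(all(res_qc$verdict == "QC_FAIL"))
  expect_true(all(!res_qc$library_qc_pass))
  # BH adjustment only fills rows that produced a p-value
  expect_warning(res_bh <- batch_screen(manifest, model, cfg, adjust_p = TRUE))
  expect_true("q_value" %in% names(res_bh))
  expect_true(is.na(res_bh$q_value[res_bh$sample_id == "broken"]))
  expect_true(all(res_bh$q_value >= res_bh$p_value, na.rm = TRUE))
})

test_that("batch_screen validates and handles degenerate manifests", {
  expect_error(batch_screen(tibble::tibble(x = 1)), "sample_id and path")
  expect_warning(
    empty <- batch_screen(tibble::tibble(sample_id = character(0),
                                         path = character(0))),
    "empty manifest"
  )
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sample_id", "p_value", "verdict") %in% names(empty)))
  # manifest can also be a TSV path
  tsv <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tpath\nx\t/nonexistent.sam", tsv)
  expect_warning(res <- batch_screen(tsv, alk_exon_model(), cfg_small()))
  expect_equal(res$verdict, "ERROR")
})

test_that("confusion metrics reproduce the packaged validation cohort outcome", {
  cohort <- validation_cohort()
  expect_equal(nrow(cohort), 50)
  expect_equal(sum(cohort$predicted_positive), 13)
  expect_equal(sum(cohort$confirmed_positive), 11)
  m <- confusion_metrics(cohort)
  expect_equal(m$tp, 11)
  expect_equal(m$fp, 2)
  expect_equal(m$tn, 37)
  expect_equal(m$fn, 0)
  expect_equal(m$accuracy, 96)
  expect_equal(m$sensitivity, 100)
  expect_equal(round(m$specificity, 1), 94.9)
})

test_that("confusion metrics on hand-checkable tables", {
  one_each <- tibble::tibble(
    predicted_positive = c(TRUE, TRUE, FALSE, FALSE),
    confirmed_positive = c(TRUE, FALSE, FALSE, TRUE)
  )
  m <- confusion_metrics(one_each)
  expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(m$accuracy, 50)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 50)
  perfect <- tibble::tibble(
    predicted_positive = c(TRUE, FALSE, TRUE),
    confirmed_positive = c(TRUE, FALSE, TRUE)
  )
  mp <- confusion_metrics(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$sensitivity, 100)
  expect_equal(mp$specificity, 100)
  expect_error(confusion_metrics(perfect[0, ]), "empty")
  expect_error(confusion_metrics(tibble::tibble(a = 1)), "needs logical columns")
  expect_error(
    confusion_metrics(tibble::tibble(
      sample_id = c("a", "a"),
      predicted_positive = c(TRUE, FALSE), confirmed_positive = c(TRUE, FALSE)
    )),
    "unique"
  )
  expect_error(
    confusion_metrics(tibble::tibble(predicted_positive = c(FALSE, FALSE),
                                     confirmed_positive = c(FALSE, FALSE))),
    "sensitivity undefined"
  )
})

test_that("coverage plots are ggplots with sense up and antisense down", {
  model <- alk_exon_model()
  cfg <- cfg_small()
  prof <- sim_profile("FUSION", model, on_target_reads = 150L,
                      background_reads = 1350L, antisense_fraction = 0.2,
                      seed = 301L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  rep <- run_sample(sam, model, cfg)
  p <- ggplot2::autoplot(rep$profile, result = rep$result)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  df <- built$data[[1]]
  # sense bars nonnegative, antisense bars nonpositive
  expect_true(all(rep$profile$norm_sense >= 0))
  expect_gt(sum(rep$profile$norm_antisense), 0) # antisense reads simulated
  expect_lt(min(df$ymin), 0)  # drawn below the axis
  expect_gt(max(df$ymax), 0)  # sense drawn above
  # plot_coverage is an alias
  expect_s3_class(plot_coverage(rep$profile), "ggplot")
})
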