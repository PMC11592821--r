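test_that("simulated SAM has the exact requested record counts", {
  prof <- sim_profile("WILD_TYPE", toy_model(), on_target_reads = 100L,
                      background_reads = 900L, read_length = 30L, seed = 7L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_length(body, 1000)
  rname <- vapply(strsplit(body, "\t"), `[[`, character(1), 3)
  expect_equal(sum(rname == "chrT"), 100)
  expect_equal(sum(rname != "chrT"), 900)
  # SILENT emits zero on-target reads regardless of the requested count
  silent <- sim_profile("SILENT", toy_model(), on_target_reads = 100L,
                        background_reads = 50L, read_length = 30L)
  sam2 <- tempfile(fileext = ".sam")
  simulate_alignments(silent, sam2, truth_path = NA)
  body2 <- readLines(sam2)
  body2 <- body2[!startsWith(body2, "@")]
  expect_length(body2, 50)
  expect_false(any(grepl("\tchrT\t", body2)))
})

test_that("same seed gives byte-identical SAM output, different seed differs", {
  prof <- sim_profile("FUSION", toy_model(), breakpoint_exon = 2L,
                      on_target_reads = 60L, background_reads = 200L,
                      read_length = 25L, seed = 99L)
  a <- tempfile(fileext = ".sam"); b <- tempfile(fileext = ".sam")
  simulate_alignments(prof, a, truth_path = NA)
  simulate_alignments(prof, b, truth_path = NA)
  expect_identical(readLines(a), readLines(b))
  prof2 <- sim_profile("FUSION", toy_model(), breakpoint_exon = 2L,
                       on_target_reads = 60L, background_reads = 200L,
                       read_length = 25L, seed = 100L)
  c_ <- tempfile(fileext = ".sam")
  simulate_alignments(prof2, c_, truth_path = NA)
  expect_false(identical(readLines(a), readLines(c_)))
})

test_that("profile weights encode the three truth shapes", {
  m <- alk_exon_model()
  fus <- sim_profile("FUSION", m, breakpoint_exon = 20L, fold = 50)
  expect_true(all(fus$exon_weights[as.character(1:19)] == 0))
  expect_true(all(fus$exon_weights[as.character(20:29)] == 50))
  leaky <- sim_profile("FUSION", m, fold = 10, leak = 0.1)
  expect_true(all(leaky$exon_weights[as.character(1:19)] == 0.1))
  wt <- sim_profile("WILD_TYPE", m, baseline = 2)
  expect_true(all(wt$exon_weights == 2))
  sil <- sim_profile("SILENT", m)
  expect_true(all(sil$exon_weights == 0))
  expect_equal(sil$on_target_reads, 0L)
  expect_error(sim_profile("FUSION", m, breakpoint_exon = 99L), "not present")
  expect_error(sim_profile("WILD_TYPE", m, antisense_fraction = 1.5), "0, 1")
})

test_that("every simulated on-target read lies fully inside one exon", {
  m <- toy_model()
  prof <- sim_profile("WILD_TYPE", m, on_target_reads = 200L,
                      background_reads = 0L, read_length = 40L, seed = 3L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  body <- readLines(sam)
  body <- body[!startsWith(body, "@")]
  f <- strsplit(body, "\t")
  pos0 <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  inside <- vapply(pos0, function(p) {
    any(p >= m$start & (p + 40L) <= m$end)
  }, logical(1))
  expect_true(all(inside))
})

test_that("antisense_fraction = 0 yields purely sense coverage", {
  m <- toy_model()
  prof <- sim_profile("WILD_TYPE", m, on_target_reads = 150L,
                      background_reads = 0L, read_length = 30L,
                      antisense_fraction = 0, seed = 5L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  counts <- count_exon_bases(sam, m, read_filter_params(), "reverse")
  expect_true(all(counts$antisense_bases == 0))
  expect_equal(sum(counts$sense_bases), 150 * 30)
  # and a heavy antisense fraction shows up on the antisense strand
  prof2 <- sim_profile("WILD_TYPE", m, on_target_reads = 150L,
                       background_reads = 0L, read_length = 30L,
                       antisense_fraction = 1, seed = 5L)
  sam2 <- tempfile(fileext = ".sam")
  simulate_alignments(prof2, sam2, truth_path = NA)
  counts2 <- count_exon_bases(sam2, m, read_filter_params(), "reverse")
  expect_true(all(counts2$sense_bases == 0))
  expect_equal(sum(counts2$antisense_bases), 150 * 30)
})

test_that("reads longer than the shortest expressed exon are refused", {
  m <- toy_model() # shortest exon is 60 bp
  prof <- sim_profile("WILD_TYPE", m, on_target_reads = 10L,
                      background_reads = 0L, read_length = 61L)
  expect_error(simulate_alignments(prof, tempfile(fileext = ".sam")),
               "shortest expressed exon")
  # FUSION restricted to the long exons tolerates the same read length
  prof2 <- sim_profile("FUSION", m, breakpoint_exon = 2L,
                       on_target_reads = 10L, background_reads = 0L,
                       read_length = 61L, seed = 2L)
  expect_no_error(simulate_alignments(prof2, tempfile(fileext = ".sam"),
                                      truth_path = NA))
})

test_that("truth sidecar records the generating parameters", {
  prof <- sim_profile("FUSION", toy_model(), breakpoint_exon = 2L,
                      on_target_reads = 20L, background_reads = 30L,
                      read_length = 25L, seed = 11L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam)
  truth <- jsonlite::read_json(paste0(sam, ".truth.json"))
  expect_equal(truth$truth_label, "FUSION")
  expect_equal(truth$on_target_reads, 20)
  expect_equal(truth$seed, 11)
  expect_equal(truth$exon_weights$`1`, 0)
})

test_that("subsampling keeps the header, is deterministic and validates size", {
  prof <- sim_profile("WILD_TYPE", toy_model(), on_target_reads = 50L,
                      background_reads = 450L, read_length = 30L, seed = 13L)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(prof, sam, truth_path = NA)
  sub1 <- subsample_sam(sam, 100, seed = 1)
  sub1b <- subsample_sam(sam, 100, seed = 1)
  sub2 <- subsample_sam(sam, 100, seed = 2)
  expect_identical(readLines(sub1), readLines(sub1b))
  expect_false(identical(readLines(sub1), readLines(sub2)))
  body <- readLines(sub1)
  expect_equal(sum(startsWith(body, "@")), 3) # @HD + two @SQ lines kept
  expect_equal(sum(!startsWith(body, "@")), 100)
  # subsampled records are a subset of the originals, order preserved
  orig <- readLines(sam); orig <- orig[!startsWith(orig, "@")]
  kept <- body[!startsWith(body, "@")]
  expect_true(all(kept %in% orig))
  expect_false(is.unsorted(match(kept, orig)))
  # full-size subsample is the identity
  all_reads <- subsample_sam(sam, 500, seed = 1)
  expect_identical(readLines(all_reads), readLines(sam))
  expect_error(subsample_sam(sam, 501, seed = 1), "only 500 available")
})

test_that("depth experiment returns the grid and summarizes into a power curve", {
  m4 <- exon_model("chrT", start = c(100L, 300L, 500L, 700L),
                   end = c(200L, 400L, 600L, 800L), gene_strand = "+")
  cfg <- assay_config(control_exons = 1:2, tk_exons = 3:4,
                      min_library_reads = 1)
  prof <- sim_profile("FUSION", m4, breakpoint_exon = 3L, fold = 20,
                      on_target_reads = 200L, background_reads = 1800L,
                      read_length = 40L, seed = 17L)
  res <- depth_reliability_experiment(prof, depth_grid = c(200, 1000),
                                      replicates = 2L, base_seed = 5L,
                                      config = cfg)
  expect_s3_class(res, "subsample_result")
  expect_equal(nrow(res), 4)
  expect_equal(sort(unique(res$target_reads)), c(200, 1000))
  expect_equal(res$seed, 5:8)
  expect_true(all(res$tk_depth >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # more reads from the same library cannot lower the median depth
  pc <- power_curve(res)
  expect_equal(nrow(pc), 2)
  expect_lte(pc$median_tk_depth[1], pc$median_tk_depth[2])
  expect_error(
    depth_reliability_experiment(prof, depth_grid = c(5000), config = cfg),
    "smaller than max"
  )
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
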