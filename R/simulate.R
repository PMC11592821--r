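#' Simulation profile for synthetic stranded RNA-seq alignments
#'
#' Describes one synthetic sample with known truth. Three coverage shapes
#' are supported: `FUSION` (5' exons before the breakpoint silenced up to a
#' configurable leak, kinase-domain and downstream exons elevated
#' `fold`-fold -- the signature of a rearrangement with the breakpoint in
#' the preceding intron), `WILD_TYPE` (uniform expression across all exons)
#' and `SILENT` (no on-target expression). Off-target background reads are
#' placed on a decoy contig so the library size and the on-target coverage
#' can be controlled independently.
#'
#' @param kind `"FUSION"`, `"WILD_TYPE"` or `"SILENT"`.
#' @param model An [exon_model()].
#' @param breakpoint_exon First elevated exon for `FUSION` (default 20, the
#'   most common ALK breakpoint: intron 19).
#' @param fold Fold elevation of post-breakpoint exons over baseline.
#' @param baseline Baseline relative expression weight.
#' @param leak Residual relative expression of pre-breakpoint exons for
#'   `FUSION`, as a fraction of baseline (default 0).
#' @param antisense_fraction Probability that an on-target read is generated
#'   in the antisense orientation (emulating read-through transcription from
#'   a neighboring opposite-strand gene).
#' @param on_target_reads,background_reads Read counts; background reads set
#'   the library size.
#' @param read_length Read length in bases.
#' @param library_strandedness Library protocol the simulated strands encode.
#' @param seed Integer seed; the emitted SAM is deterministic given the seed.
#' @return A list of class `sim_profile` with per-exon `exon_weights`.
#' @export
sim_profile <- function(kind = c("FUSION", "WILD_TYPE", "SILENT"),
                        model = alk_exon_model(),
                        breakpoint_exon = 20L,
                        fold = 50,
                        baseline = 1,
                        leak = 0,
                        antisense_fraction = 0,
                        on_target_reads = 300L,
                        background_reads = 199700L,
                        read_length = 50L,
                        library_strandedness = c("reverse", "forward", "unstranded"),
                        seed = 1L) {
  kind <- match.arg(kind)
  library_strandedness <- match.arg(library_strandedness)
  if (kind == "FUSION" && !breakpoint_exon %in% model$exon_number) {
    rlang::abort("breakpoint_exon not present in the gene model")
  }
  if (fold <= 0) rlang::abort("fold must be positive")
  if (antisense_fraction < 0 || antisense_fraction > 1) {
    rlang::abort("antisense_fraction must be in [0, 1]")
  }
  weights <- switch(kind,
    FUSION = ifelse(model$exon_number >= breakpoint_exon,
                    fold * baseline, leak * baseline),
    WILD_TYPE = rep(baseline, nrow(model)),
    SILENT = rep(0, nrow(model))
  )
  if (kind == "SILENT") on_target_reads <- 0L
  if (kind != "SILENT" && sum(weights) <= 0) {
    rlang::abort("exon weights must have positive total unless SILENT")
  }
  structure(
    list(
      truth_label = kind,
      model = model,
      exon_weights = stats::setNames(weights, model$exon_number),
      antisense_fraction = antisense_fraction,
      on_target_reads = as.integer(on_target_reads),
      background_reads = as.integer(background_reads),
      read_length = as.integer(read_length),
      library_strandedness = library_strandedness,
      seed = as.integer(seed)
    ),
    class = "sim_profile"
  )
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf(
    "<sim_profile> %s: %d on-target + %d background reads (%d bp, %s-stranded, seed %d)\n",
    x$truth_label, x$on_target_reads, x$background_reads, x$read_length,
    x$library_strandedness, x$seed
  ))
  invisible(x)
}

decoy_contig <- "sim_decoy"
decoy_length <- 1000000L

#' Simulate stranded alignments as a SAM file with known truth
#'
#' Emits a coordinate-sorted, syntactically valid SAM file. On-target reads
#' are drawn per exon proportionally to `weight * length`, start uniformly
#' within the exon so the read fits entirely inside it (no splice
#' simulation), carry MAPQ 255, and have their alignment strand set so that
#' the configured library convention labels them SENSE -- except for an
#' `antisense_fraction` labeled ANTISENSE. Background reads are placed
#' uniformly on a decoy contig. Byte-identical output given the same seed.
#'
#' @param profile A [sim_profile()].
#' @param sam_path Output SAM path.
#' @param truth_path Optional JSON path for the truth record (defaults to
#'   `<sam_path>.truth.json`; `NA` suppresses it).
#' @return `sam_path`, invisibly.
#' @export
simulate_alignments <- function(profile, sam_path,
                                truth_path = paste0(sam_path, ".truth.json")) {
  model <- profile$model
  rl <- profile$read_length
  w <- profile$exon_weights
  active <- which(w > 0)
  if (length(active) > 0 && profile$on_target_reads > 0) {
    too_short <- model$length[active] < rl
    if (any(too_short)) {
      rlang::abort(paste0(
        "read_length ", rl, " exceeds the shortest expressed exon (",
        min(model$length[active]),
        " bp); shrink read_length so reads fit inside exons"
      ))
    }
  }
  chrom <- attr(model, "chrom")
  gene_strand <- attr(model, "gene_strand")
  lib <- profile$library_strandedness

  records <- withr::with_seed(profile$seed, {
    recs <- character(0)
    if (profile$on_target_reads > 0) {
      prob <- w[active] * model$length[active]
      exon_idx <- active[sample.int(length(active), profile$on_target_reads,
                                    replace = TRUE, prob = prob)]
      offset <- vapply(model$length[exon_idx] - rl + 1L,
                       function(m) sample.int(m, 1L), integer(1))
      pos <- model$start[exon_idx] + offset # 1-based POS
      antisense <- stats::runif(profile$on_target_reads) < profile$antisense_fraction
      # forward-strand alignment makes a read SENSE when the truth table says so
      sense_forward <- switch(lib,
        reverse = gene_strand == "-",
        forward = gene_strand == "+",
        unstranded = TRUE
      )
      forward <- ifelse(antisense, !sense_forward, sense_forward)
      o <- order(pos)
      recs <- c(recs, sam_record(
        qname = sprintf("t%06d", seq_len(profile$on_target_reads))[o],
        flag = ifelse(forward, 0L, 16L)[o],
        rname = chrom, pos = pos[o], rl = rl
      ))
    }
    if (profile$background_reads > 0) {
      pos <- sample.int(decoy_length - rl, profile$background_reads, replace = TRUE)
      forward <- stats::runif(profile$background_reads) < 0.5
      o <- order(pos)
      recs <- c(recs, sam_record(
        qname = sprintf("b%06d", seq_len(profile$background_reads))[o],
        flag = ifelse(forward, 0L, 16L)[o],
        rname = decoy_contig, pos = pos[o], rl = rl
      ))
    }
    recs
  })

  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, max(model$end) + 1000L),
    sprintf("@SQ\tSN:%s\tLN:%d", decoy_contig, decoy_length)
  )
  writeLines(c(header, records), sam_path)

  if (!is.na(truth_path)) {
    jsonlite::write_json(
      list(
        truth_label = profile$truth_label,
        gene_id = attr(model, "gene_id"),
        on_target_reads = profile$on_target_reads,
        background_reads = profile$background_reads,
        antisense_fraction = profile$antisense_fraction,
        read_length = profile$read_length,
        library_strandedness = profile$library_strandedness,
        seed = profile$seed,
        exon_weights = as.list(profile$exon_weights)
      ),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(sam_path)
}

sam_record <- function(qname, flag, rname, pos, rl) {
  seq <- strrep("A", rl)
  qual <- strrep("I", rl)
  sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, rl, seq, qual)
}

#' Subsample reads from a SAM file without replacement
#'
#' Uniform sample of the alignment records (header kept, record order
#' preserved so coordinate sorting survives). Deterministic given the seed.
#' Emulates sequencing the same library at lower depth.
#'
#' @param sam_path Input SAM file.
#' @param target_read_count Number of records to keep; must not exceed the
#'   number available.
#' @param seed Integer seed.
#' @param out_path Output SAM path.
#' @return `out_path`, invisibly.
#' @export
subsample_sam <- function(sam_path, target_read_count, seed,
                          out_path = tempfile(fileext = ".sam")) {
  lines <- readLines(sam_path)
  is_header <- startsWith(lines, "@")
  body <- lines[!is_header]
  if (target_read_count > length(body)) {
    rlang::abort(sprintf("requested %d reads but only %d available",
                         target_read_count, length(body)))
  }
  keep <- withr::with_seed(seed,
    sort(sample.int(length(body), target_read_count))
  )
  writeLines(c(lines[is_header], body[keep]), out_path)
  invisible(out_path)
}

#' Sequencing-depth reliability experiment
#'
#' Desk-scale version of the subsampling experiment that calibrates the
#' kinase-domain depth reliability gate: simulate one master library from a
#' profile, subsample it to each target read count in `depth_grid` (in
#' triplicate by default, mirroring the published design of 1/2/5/10/20
#' million reads in triplicate -- reproduced here in shape, not magnitude),
#' and for each subsample compute the kinase-domain depth and the exact
#' one-sided asymmetry p-value.
#'
#' @param profile A [sim_profile()]; its total read count must cover
#'   `max(depth_grid)`.
#' @param depth_grid Target read counts (total reads per subsample).
#' @param replicates Subsamples per grid point.
#' @param base_seed Base seed; replicate seeds are derived as
#'   `base_seed + replicate index` and logged in the output.
#' @param config An [assay_config()]; supplies exon groups, filters and alpha.
#' @return A tibble of class `subsample_result` with columns `target_reads`,
#'   `replicate`, `seed`, `tk_depth`, `p_value`, plus attributes `alpha` and
#'   `truth_label`. See [power_curve()] for the per-depth summary.
#' @export
depth_reliability_experiment <- function(profile,
                                         depth_grid = c(10e3, 20e3, 50e3, 100e3, 200e3),
                                         replicates = 3L,
                                         base_seed = 1L,
                                         config = assay_config()) {
  if (length(depth_grid) == 0) rlang::abort("depth_grid must be non-empty")
  total <- profile$on_target_reads + profile$background_reads
  if (max(depth_grid) > total) {
    rlang::abort("profile total reads smaller than max(depth_grid)")
  }
  model <- profile$model
  check_config_against_model(config, model)
  params <- filter_params_from_config(config)
  master_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(c(master_sam, paste0(master_sam, ".truth.json"))), add = TRUE)
  simulate_alignments(profile, master_sam)

  grid <- tidyr::expand_grid(
    target_reads = sort(depth_grid),
    replicate = seq_len(replicates)
  )
  grid$seed <- base_seed + seq_len(nrow(grid)) - 1L
  res <- purrr::pmap_dfr(grid, function(target_reads, replicate, seed) {
    sub <- subsample_sam(master_sam, target_reads, seed)
    on.exit(unlink(sub), add = TRUE)
    bam <- as_indexed_bam(sub)
    counts <- count_exon_bases(bam, model, params, config$library_strandedness)
    n <- library_size(bam, params)
    prof <- normalize_profile(counts, n)
    test <- exact_mwu_one_sided(
      prof$norm_sense[match(config$control_exons, prof$exon_number)],
      prof$norm_sense[match(config$tk_exons, prof$exon_number)]
    )
    tibble::tibble(
      target_reads = target_reads,
      replicate = replicate,
      seed = seed,
      tk_depth = tk_depth(prof, config$tk_exons,
                          both_strands = config$depth_both_strands),
      p_value = test$p_value
    )
  })
  tibble::new_tibble(res,
    alpha = config$alpha,
    min_tk_depth = config$min_tk_depth,
    truth_label = profile$truth_label,
    class = "subsample_result"
  )
}

#' Power curve of a depth-reliability experiment
#'
#' @param result A `subsample_result` tibble from
#'   [depth_reliability_experiment()].
#' @return A tibble with one row per grid point: median kinase-domain depth,
#'   median p-value and the fraction of replicates significant at the
#'   configured alpha.
#' @export
power_curve <- function(result) {
  alpha <- attr(result, "alpha")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(result), .data$target_reads),
    median_tk_depth = stats::median(.data$tk_depth),
    median_p = stats::median(.data$p_value),
    power = mean(.data$p_value < alpha),
    .groups = "drop"
  )
}

#' Plot p-value against kinase-domain depth for a subsampling experiment
#'
#' @param object A `subsample_result` tibble.
#' @param ... Unused.
#' @return A ggplot: p-value (log scale) vs kinase-domain depth, with the
#'   significance level and the depth reliability gate drawn as reference
#'   lines.
#' @method autoplot subsample_result
#' @export
autoplot.subsample_result <- function(object, ...) {
  alpha <- attr(object, "alpha")
  gate <- attr(object, "min_tk_depth")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$tk_depth, y = .data$p_value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$target_reads)),
                        size = 2) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = gate, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "kinase-domain depth (mean bases/position, exons 20-24)",
      y = "asymmetry p-value",
      colour = "subsampled reads",
      title = paste0("Depth reliability (truth: ", attr(object, "truth_label"), ")")
    ) +
    ggplot2::theme_minimal()
}
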