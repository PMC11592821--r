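#' Assay configuration: exon groups, thresholds and read filters
#'
#' All tunables of the coverage-asymmetry assay in one place. Defaults encode
#' the published ALK assay: control (pre-kinase) exons 2-6, kinase-domain test
#' exons 20-24, one-sided significance level 0.05, kinase-domain depth
#' reliability gate 0.7 mean bases/position, library QC floor of 2.5 million
#' usable reads, mapping-quality filter MQ > 100 (i.e. `min_mapq = 101`,
#' which selects STAR unique mappers at MAPQ 255), minimum aligned length
#' 10 bp, and a reverse-stranded library.
#'
#' @param control_exons Integer vector of pre-kinase control exon numbers.
#' @param tk_exons Integer vector of kinase-domain test exon numbers.
#' @param alpha One-sided significance level for the asymmetry call.
#' @param min_tk_depth Reliability gate: minimum mean aligned bases per
#'   position over `tk_exons` below which calls are annotated unreliable.
#' @param min_library_reads Library QC floor (usable reads genome-wide).
#' @param min_mapq Minimum mapping quality (inclusive); 101 encodes the
#'   strict "MQ > 100" rule.
#' @param min_aln_len Minimum reference-aligned length in bases (inclusive).
#' @param library_strandedness `"reverse"`, `"forward"` or `"unstranded"`.
#' @param expression_floor Normalized-coverage floor separating the
#'   wild-type-expression call from the not-expressed call when no asymmetry
#'   is found. Heuristic; see the methods vignette.
#' @param depth_both_strands Count both strands in the kinase-domain depth
#'   metric (default `FALSE`: sense bases only).
#'
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(control_exons = 2:6,
                         tk_exons = 20:24,
                         alpha = 0.05,
                         min_tk_depth = 0.7,
                         min_library_reads = 2.5e6,
                         min_mapq = 101L,
                         min_aln_len = 10L,
                         library_strandedness = c("reverse", "forward", "unstranded"),
                         expression_floor = 0.01,
                         depth_both_strands = FALSE) {
  library_strandedness <- match.arg(library_strandedness)
  control_exons <- sort(unique(as.integer(control_exons)))
  tk_exons <- sort(unique(as.integer(tk_exons)))
  if (length(control_exons) == 0 || length(tk_exons) == 0) {
    rlang::abort("control_exons and tk_exons must both be non-empty")
  }
  if (length(intersect(control_exons, tk_exons)) > 0) {
    rlang::abort("control_exons and tk_exons must be disjoint")
  }
  if (!(alpha > 0 && alpha < 1)) rlang::abort("alpha must be in (0, 1)")
  if (min_tk_depth < 0) rlang::abort("min_tk_depth must be >= 0")
  if (min_aln_len < 1) rlang::abort("min_aln_len must be >= 1")
  if (min_mapq < 0) rlang::abort("min_mapq must be >= 0")
  structure(
    list(
      control_exons = control_exons,
      tk_exons = tk_exons,
      alpha = alpha,
      min_tk_depth = min_tk_depth,
      min_library_reads = min_library_reads,
      min_mapq = as.integer(min_mapq),
      min_aln_len = as.integer(min_aln_len),
      library_strandedness = library_strandedness,
      expression_floor = expression_floor,
      depth_both_strands = isTRUE(depth_both_strands)
    ),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("<assay_config>\n")
  cat(sprintf("  control exons: %s\n", paste(x$control_exons, collapse = ",")))
  cat(sprintf("  TK exons:      %s\n", paste(x$tk_exons, collapse = ",")))
  cat(sprintf("  alpha=%.3g  min_tk_depth=%.3g  min_library_reads=%.3g\n",
              x$alpha, x$min_tk_depth, x$min_library_reads))
  cat(sprintf("  read filters: MAPQ >= %d, aligned length >= %d bp\n",
              x$min_mapq, x$min_aln_len))
  cat(sprintf("  library: %s-stranded\n", x$library_strandedness))
  invisible(x)
}

# check that the configured exon groups exist in a model
check_config_against_model <- function(config, model) {
  missing <- setdiff(c(config$control_exons, config$tk_exons), model$exon_number)
  if (length(missing) > 0) {
    rlang::abort(paste0("configuration error: exon group members absent from the gene model: ",
                        paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read an assay configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [assay_config()] field-for-field;
#' keys not present keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `assay_config` list.
#' @export
read_assay_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(assay_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(assay_config, raw)
}
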