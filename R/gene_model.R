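#' Construct an exon model for a single transcript
#'
#' An exon model is the ordered, numbered exon structure of one transcript:
#' a tibble with one row per exon (columns `exon_number`, `start`, `end`,
#' `length`) carrying the gene identity, chromosome and gene strand as
#' attributes. Coordinates are stored 0-based half-open, the convention used
#' by alignment files, so exon length is simply `end - start`. Exon numbering
#' always follows transcription order: for a minus-strand gene exon 1 is the
#' exon with the largest genomic coordinate.
#'
#' @param chrom Chromosome (contig) name as it appears in the alignment file.
#' @param start,end Integer vectors of 0-based half-open exon coordinates.
#' @param gene_strand `"+"` or `"-"`; the genomic strand the gene is
#'   transcribed from.
#' @param gene_id,transcript_id Identifiers carried through to reports.
#' @param exon_number Optional explicit numbering (1..N in transcription
#'   order). When `NULL`, numbering is derived from the coordinates and the
#'   strand.
#'
#' @return A tibble of class `exon_model`, one row per exon, sorted by
#'   `exon_number`.
#' @export
#' @examples
#' exon_model("chr2", start = c(100, 300), end = c(200, 400),
#'            gene_strand = "-", gene_id = "ALK", transcript_id = "tx1")
exon_model <- function(chrom, start, end, gene_strand,
                       gene_id = NA_character_, transcript_id = NA_character_,
                       exon_number = NULL) {
  stopifnot(length(start) == length(end), length(start) >= 1)
  if (!gene_strand %in% c("+", "-")) {
    rlang::abort("gene_strand must be '+' or '-'")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end <= start)) rlang::abort("malformed model: exon with end <= start")
  if (is.null(exon_number)) {
    exon_number <- if (gene_strand == "+") rank(start) else rank(-start)
  }
  exon_number <- as.integer(exon_number)
  tbl <- tibble::tibble(
    exon_number = exon_number,
    start = start,
    end = end,
    length = end - start
  )
  tbl <- dplyr::arrange(tbl, .data$exon_number)
  out <- tibble::new_tibble(
    tbl,
    chrom = as.character(chrom)[1],
    gene_strand = gene_strand,
    gene_id = gene_id,
    transcript_id = transcript_id,
    class = "exon_model"
  )
  validate_exon_model(out)
}

validate_exon_model <- function(model) {
  n <- nrow(model)
  if (!identical(sort(model$exon_number), seq_len(n))) {
    rlang::abort("malformed model: exon numbers must be exactly 1..N")
  }
  if (any(model$end <= model$start)) {
    rlang::abort("malformed model: exon with end <= start")
  }
  o <- order(model$start)
  if (any(model$end[o][-n] > model$start[o][-1])) {
    rlang::abort("malformed model: overlapping exons")
  }
  # transcription order must match the strand
  first <- model$start[model$exon_number == 1L]
  extreme <- if (attr(model, "gene_strand") == "+") min(model$start) else max(model$start)
  if (first != extreme) {
    rlang::abort("malformed model: exon 1 is not at the transcription start")
  }
  model
}

#' @export
print.exon_model <- function(x, ...) {
  cat(sprintf(
    "<exon_model> %s (%s), %s%s, %d exons, %d exonic bases\n",
    attr(x, "gene_id"), attr(x, "transcript_id"),
    attr(x, "chrom"), attr(x, "gene_strand"),
    nrow(x), sum(x$length)
  ))
  NextMethod()
}

#' Load an exon model from GTF, BED12 or an exon-table TSV
#'
#' GTF input is Ensembl-dialect 1-based closed and converted to the internal
#' 0-based half-open convention on load; BED12 block coordinates are already
#' 0-based half-open and taken as-is; the exon-table format is the package's
#' own round-trippable TSV (see [write_exon_model()]). In every case exon
#' numbering is recomputed from transcription order, so "exons 20-24" always
#' means the same biological exons regardless of genomic strand.
#'
#' @param path Path to the annotation file.
#' @param format One of `"GTF"`, `"BED12"`, `"exon-table"`. Default guesses
#'   from the file extension.
#' @param transcript_id Transcript to extract (required for GTF files that
#'   contain more than one transcript).
#'
#' @return An [exon_model()] tibble.
#' @export
read_exon_model <- function(path, format = c("auto", "GTF", "BED12", "exon-table"),
                            transcript_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gtf = "GTF", gff = "GTF",
      bed = "BED12",
      tsv = "exon-table", txt = "exon-table",
      rlang::abort(paste0("cannot guess annotation format from extension '", ext,
                          "'; pass format explicitly"))
    )
  }
  switch(format,
    "GTF" = read_model_gtf(path, transcript_id),
    "BED12" = read_model_bed12(path, transcript_id),
    "exon-table" = read_model_exon_table(path)
  )
}

read_model_gtf <- function(path, transcript_id) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!is.null(transcript_id)) {
    gr <- gr[!is.na(gr$transcript_id) & gr$transcript_id == transcript_id]
  } else {
    tx <- unique(gr$transcript_id)
    if (length(tx) > 1) {
      rlang::abort("GTF contains multiple transcripts; pass transcript_id")
    }
    transcript_id <- tx
  }
  if (length(gr) == 0) rlang::abort("transcript not found")
  strand <- as.character(unique(GenomicRanges::strand(gr)))
  if (length(strand) != 1 || !strand %in% c("+", "-")) {
    rlang::abort("malformed model: exon strands inconsistent or unstranded")
  }
  gid <- if (!is.null(gr$gene_id)) unique(gr$gene_id)[1] else NA_character_
  # GRanges from GTF are 1-based closed; convert to 0-based half-open
  exon_model(
    chrom = as.character(GenomicRanges::seqnames(gr))[1],
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_strand = strand,
    gene_id = gid,
    transcript_id = transcript_id
  )
}

read_model_bed12 <- function(path, transcript_id = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(transcript_id) && !is.null(gr$name)) {
    gr <- gr[gr$name == transcript_id]
  }
  if (length(gr) == 0) rlang::abort("transcript not found")
  if (length(gr) > 1) rlang::abort("BED12 contains multiple records; pass transcript_id")
  blocks <- unlist(gr$blocks)
  abs_start <- GenomicRanges::start(gr) - 1L + IRanges::start(blocks) - 1L
  abs_end <- abs_start + IRanges::width(blocks)
  exon_model(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = abs_start,
    end = abs_end,
    gene_strand = as.character(GenomicRanges::strand(gr)),
    gene_id = NA_character_,
    transcript_id = if (!is.null(gr$name)) gr$name else NA_character_
  )
}

read_model_exon_table <- function(path) {
  lines <- readLines(path, n = 1L)
  meta <- parse_exon_table_header(lines[1])
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "exon_number")
  if (!all(need %in% names(tab))) {
    rlang::abort("malformed model: exon table must have columns chrom, start, end, exon_number")
  }
  exon_model(
    chrom = tab$chrom[1],
    start = tab$start,
    end = tab$end,
    gene_strand = meta[["gene_strand"]],
    gene_id = meta[["gene_id"]],
    transcript_id = meta[["transcript_id"]],
    exon_number = tab$exon_number
  )
}

parse_exon_table_header <- function(line) {
  if (!startsWith(line, "#")) {
    rlang::abort("malformed model: exon table must start with a '# key=value ...' header line")
  }
  fields <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  out <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  if (!"gene_strand" %in% names(out)) {
    rlang::abort("malformed model: exon table header lacks gene_strand")
  }
  for (k in c("gene_id", "transcript_id")) if (!k %in% names(out)) out[k] <- NA_character_
  out
}

#' Write an exon model to the exon-table TSV format
#'
#' The exon-table format is a 4-column TSV (`chrom`, `start`, `end`,
#' `exon_number`; 0-based half-open coordinates) preceded by a two-line
#' header: a `# key=value` metadata line carrying `gene_id`,
#' `transcript_id` and `gene_strand`, then the column names. Reloading with
#' [read_exon_model()] reproduces the model exactly.
#'
#' @param model An [exon_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exon_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# gene_id=%s transcript_id=%s gene_strand=%s coords=0-based-half-open",
    attr(model, "gene_id"), attr(model, "transcript_id"), attr(model, "gene_strand")
  ), con)
  writeLines("chrom\tstart\tend\texon_number", con)
  utils::write.table(
    data.frame(chrom = attr(model, "chrom"), start = model$start,
               end = model$end, exon_number = model$exon_number),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Built-in ALK exon model
#'
#' Returns the packaged 29-exon model of the canonical ALK transcript
#' (ENST00000389048.8): chromosome 2, minus strand, tyrosine-kinase domain
#' encoded by exons 20-29. No download is needed at runtime. The packaged
#' coordinates are a synthetic reconstruction -- exon count, chromosome,
#' strand and realistic exon lengths are preserved, but the absolute genomic
#' positions are stand-ins, which has no effect on any coverage statistic
#' (only exon lengths and read-exon overlap enter the computation).
#'
#' @return An [exon_model()] with 29 exons.
#' @export
#' @examples
#' alk <- alk_exon_model()
#' nrow(alk) # 29
alk_exon_model <- function() {
  path <- system.file("extdata", "alk_exons_synthetic.tsv", package = "covasym",
                      mustWork = TRUE)
  read_exon_model(path, format = "exon-table")
}

#' Exon lengths for a set of exon numbers
#'
#' @param model An [exon_model()].
#' @param numbers Integer vector of exon numbers; all must exist in the model.
#' @return A named integer vector mapping exon number to length in bases.
#' @export
exon_lengths <- function(model, numbers) {
  numbers <- as.integer(numbers)
  if (length(numbers) == 0) return(stats::setNames(integer(0), character(0)))
  idx <- match(numbers, model$exon_number)
  if (anyNA(idx)) {
    rlang::abort(paste0("unknown exon number(s): ",
                        paste(numbers[is.na(idx)], collapse = ", ")))
  }
  stats::setNames(model$length[idx], numbers)
}

# GRanges view of the model (internal), in genomic coordinate order
model_granges <- function(model) {
  GenomicRanges::GRanges(
    seqnames = attr(model, "chrom"),
    ranges = IRanges::IRanges(start = model$start + 1L, end = model$end),
    exon_number = model$exon_number
  )
}
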