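# Shared fixtures and independent brute-force oracles.
#
# The oracles below deliberately re-derive results with the most naive
# algorithm available (per-position marking, plain-loop enumeration) so that
# they share no code path with the package implementation.

# ---- tiny hand-written gene model: chrT, minus strand, 3 exons -------------
# genomic intervals (0-based half-open): (100,200), (300,400), (500,560)
# transcription order on '-': exon 1 = (500,560), exon 2 = (300,400),
# exon 3 = (100,200)
toy_model <- function() {
  exon_model("chrT", start = c(100L, 300L, 500L), end = c(200L, 400L, 560L),
             gene_strand = "-", gene_id = "TOY", transcript_id = "toy-tx")
}

# write a SAM file from a data frame of record fields
write_sam <- function(records, path,
                      contigs = c(chrT = 1000L, chrU = 5000L)) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
    records$qname, records$flag, records$rname, records$pos, records$mapq,
    records$cigar
  )
  writeLines(c(header, body), path)
  path
}

# SAM fixture exercising filters, strands, splicing, indels and boundaries
toy_sam_records <- function() {
  rec <- function(qname, flag, rname, pos, mapq, cigar) {
    data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
               mapq = mapq, cigar = cigar, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    rec("inside_ex3", 0L, "chrT", 121L, 255L, "50M"),        # fully in exon 3, sense
    rec("boundary_ex3", 16L, "chrT", 191L, 255L, "30M"),     # 10 bp overlap, antisense
    rec("spliced_13", 0L, "chrT", 171L, 255L, "30M300N20M"), # exon3 +30, exon1 +20, skips exon2
    rec("low_mapq", 0L, "chrT", 121L, 100L, "50M"),          # fails MQ > 100
    rec("too_short", 0L, "chrT", 131L, 255L, "9M"),          # fails >= 10 bp
    rec("dup_flagged", 1024L, "chrT", 141L, 255L, "50M"),    # duplicate
    rec("secondary", 256L, "chrT", 141L, 255L, "50M"),       # secondary
    rec("whole_ex1", 0L, "chrT", 501L, 255L, "60M"),         # all of exon 1
    rec("half_in_ex2", 0L, "chrT", 281L, 255L, "40M"),       # 20 bp into exon 2
    rec("with_del", 0L, "chrT", 311L, 255L, "10M5D10M"),     # D consumes reference
    rec("with_ins", 16L, "chrT", 351L, 255L, "5S20M3I17M"),  # S/I do not
    rec("mate2_rev", 145L, "chrT", 105L, 255L, "20M"),       # paired read 2, flipped
    rec("offtarget1", 0L, "chrU", 1001L, 255L, "50M"),
    rec("offtarget2", 16L, "chrU", 2001L, 255L, "50M"),
    rec("offtarget_dup", 1024L, "chrU", 3001L, 255L, "50M")
  ))
}

# ---- brute-force per-position coverage oracle ------------------------------
# Walks each CIGAR character by character, marks covered reference positions
# in a logical vector, then counts marks inside each exon, split by the
# transcript-orientation truth table applied to the flag bits.
oracle_exon_counts <- function(records, model,
                               min_mapq = 101L, min_aln_len = 10L,
                               library = "reverse") {
  n_ex <- nrow(model)
  sense <- antisense <- numeric(n_ex)
  gene_strand <- attr(model, "gene_strand")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (bitwAnd(r$flag, 4L) != 0L) next               # unmapped
    if (bitwAnd(r$flag, 256L) != 0L) next             # secondary
    if (bitwAnd(r$flag, 2048L) != 0L) next            # supplementary
    if (bitwAnd(r$flag, 1024L) != 0L) next            # duplicate
    if (r$mapq < min_mapq) next
    if (r$rname != attr(model, "chrom")) next
    ops <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))[[1]]
    pos <- r$pos - 1L                                  # 0-based
    covered <- integer(0)
    aln_len <- 0L
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X", "D")) {
        covered <- c(covered, seq.int(pos, pos + len - 1L))
        aln_len <- aln_len + len
        pos <- pos + len
      } else if (type == "N") {
        pos <- pos + len
      } # S, I, H, P: no reference positions
    }
    if (aln_len < min_aln_len) next
    reverse_bit <- bitwAnd(r$flag, 16L) != 0L
    read2 <- bitwAnd(r$flag, 1L) != 0L && bitwAnd(r$flag, 128L) != 0L
    fragment_forward <- if (read2) reverse_bit else !reverse_bit
    orient <- if (library == "unstranded") {
      "SENSE"
    } else {
      same <- fragment_forward == (gene_strand == "+")
      if (library == "reverse") {
        if (same) "ANTISENSE" else "SENSE"
      } else {
        if (same) "SENSE" else "ANTISENSE"
      }
    }
    for (e in seq_len(n_ex)) {
      hit <- sum(covered >= model$start[e] & covered < model$end[e])
      if (orient == "SENSE") sense[e] <- sense[e] + hit
      else antisense[e] <- antisense[e] + hit
    }
  }
  list(sense = stats::setNames(sense, model$exon_number),
       antisense = stats::setNames(antisense, model$exon_number))
}

# ---- brute-force exact Mann-Whitney oracle ---------------------------------
# Direct double-loop mid-rank U and full enumeration of group reassignments.
oracle_mwu_p <- function(control, tk) {
  u_direct <- function(ctrl, tkv) {
    u <- 0
    for (cv in ctrl) {
      for (tv in tkv) {
        if (tv > cv) u <- u + 1 else if (tv == cv) u <- u + 0.5
      }
    }
    u
  }
  pooled <- c(control, tk)
  obs <- u_direct(control, tk)
  splits <- utils::combn(length(pooled), length(tk))
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    idx <- splits[, j]
    if (u_direct(pooled[-idx], pooled[idx]) >= obs - 1e-9) hits <- hits + 1
  }
  list(u = obs, p = hits / ncol(splits))
}

# simulate one sample and classify it through the full file-based pipeline
simulate_and_classify <- function(kind, model, config, seed,
                                  on_target = 150L, background = 1350L,
                                  ...) {
  prof <- sim_profile(kind, model, on_target_reads = on_target,
                      background_reads = background, seed = seed, ...)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(c(sam, paste0(sam, ".truth.json"))))
  simulate_alignments(prof, sam)
  run_sample(sam, model, config)$result
}
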