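## SAM emission and ingestion. Simulated alignments are written as headered
## SAM with SA tags (primary record soft-clipped with the full read
## sequence, supplementary records hard-clipped); external SAM/BAM is read
## back through Rsamtools into the package's alignment-block data.frame.

cigar_for_block <- function(lead, m, trail, hard = FALSE) {
  op <- if (hard) "H" else "S"
  paste0(ifelse(lead > 0, paste0(lead, op), ""),
         m, "M",
         ifelse(trail > 0, paste0(trail, op), ""))
}

## record-orientation clip lengths: for a reverse-strand record the SAM
## sequence is the reverse complement of the read, so the clips swap ends.
record_clips <- function(read_start, read_end, read_len, strand) {
  lead <- ifelse(strand == "+", read_start - 1, read_len - read_end)
  trail <- ifelse(strand == "+", read_len - read_end, read_start - 1)
  cbind(lead = lead, trail = trail)
}

#' Write simulated long-read alignments as SAM
#'
#' One primary record per read (soft-clipped, full sequence) plus one
#' supplementary record per additional alignment block (hard-clipped), all
#' carrying SA tags, against the un-rearranged reference.
#'
#' @param sim result of [simulate_long_reads()] (fields `alignments`,
#'   `reads`).
#' @param path output SAM path.
#' @param ref_name reference sequence name for the header.
#' @param ref_len reference sequence length for the header.
#' @param sort_by_pos sort records by position (TRUE) or keep read grouping.
#' @return the path, invisibly.
#' @export
write_sam <- function(sim, path, ref_name = sim$alignments$ref[1],
                      ref_len = max(sim$alignments$ref_end),
                      sort_by_pos = TRUE) {
  aln <- sim$alignments
  reads <- sim$reads
  seq_of <- stats::setNames(reads$seq, reads$read_id)
  cl <- record_clips(aln$read_start, aln$read_end, aln$read_len, aln$strand)
  m <- aln$read_end - aln$read_start + 1
  sa_item <- paste0(aln$ref, ",", format(aln$ref_start, scientific = FALSE,
                                         trim = TRUE), ",",
                    aln$strand, ",",
                    cigar_for_block(cl[, "lead"], m, cl[, "trail"]),
                    ",60,0")
  recs <- vapply(seq_len(nrow(aln)), function(i) {
    others <- which(aln$read_id == aln$read_id[i])
    others <- setdiff(others, i)
    flag <- 0L
    if (aln$strand[i] == "-") flag <- flag + 16L
    if (!aln$primary[i]) flag <- flag + 2048L
    if (aln$primary[i]) {
      s <- seq_of[[aln$read_id[i]]]
      if (aln$strand[i] == "-") s <- revcomp(s)
      cig <- cigar_for_block(cl[i, "lead"], m[i], cl[i, "trail"], hard = FALSE)
    } else {
      s <- aln$bases[i]
      cig <- cigar_for_block(cl[i, "lead"], m[i], cl[i, "trail"], hard = TRUE)
    }
    tag <- if (length(others))
      paste0("\tSA:Z:", paste0(sa_item[others], collapse = ";"), ";")
    else ""
    paste0(aln$read_id[i], "\t", flag, "\t", aln$ref[i], "\t",
           format(aln$ref_start[i], scientific = FALSE), "\t60\t", cig,
           "\t*\t0\t0\t", s, "\t*", tag)
  }, character(1))
  if (sort_by_pos) recs <- recs[order(aln$ref_start)]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", ref_name, "\tLN:",
                     format(ref_len, scientific = FALSE)))
  writeLines(c(header, recs), path)
  invisible(path)
}

cigar_lengths <- function(cigar) {
  ops <- gsub("[0-9]+", "", cigar)
  nums <- as.numeric(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " ")[[1]])
  list(ops = strsplit(ops, "")[[1]], nums = nums)
}

## reference-aligned bases and geometry from one SAM record
decode_record <- function(pos, cigar, seq, flag) {
  cl <- cigar_lengths(cigar)
  ref_len <- sum(cl$nums[cl$ops %in% c("M", "D", "N", "=", "X")])
  lead <- if (cl$ops[1] %in% c("S", "H")) cl$nums[1] else 0
  k <- length(cl$ops)
  trail <- if (cl$ops[k] %in% c("S", "H")) cl$nums[k] else 0
  q_len <- sum(cl$nums[cl$ops %in% c("M", "I", "S", "=", "X")])
  read_len <- q_len + sum(cl$nums[cl$ops == "H"])
  ## walk CIGAR to build the reference-forward aligned string
  qpos <- if (cl$ops[1] == "S") cl$nums[1] + 1 else 1
  out <- character(0)
  for (j in seq_along(cl$ops)) {
    op <- cl$ops[j]; n <- cl$nums[j]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, substr(seq, qpos, qpos + n - 1))
      qpos <- qpos + n
    } else if (op %in% c("D", "N")) {
      out <- c(out, strrep("N", n))
    } else if (op %in% c("I")) {
      qpos <- qpos + n
    } else if (op == "S" && j > 1) {
      qpos <- qpos + n
    }
  }
  strand <- if (bitwAnd(flag, 16L)) "-" else "+"
  aligned_q <- sum(cl$nums[cl$ops %in% c("M", "I", "=", "X")])
  if (strand == "+") {
    read_start <- lead + 1
    read_end <- lead + aligned_q
  } else {
    read_start <- trail + 1
    read_end <- trail + aligned_q
  }
  list(ref_start = pos, ref_end = pos + ref_len - 1, strand = strand,
       read_start = read_start, read_end = read_end, read_len = read_len,
       bases = paste(out, collapse = ""))
}

#' Read long-read alignments from SAM/BAM
#'
#' Parses primary and supplementary records (secondary alignments and
#' unmapped reads are dropped, with a count reported via message) into the
#' package's alignment-block data.frame. SAM input is converted through
#' [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @return alignment-block data.frame (see [simulate_long_reads()]).
#' @export
read_long_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  secondary <- bitwAnd(flag, 256L) > 0
  unmapped <- bitwAnd(flag, 4L) > 0
  drop <- secondary | unmapped | is.na(b$pos)
  if (any(unmapped))
    message(sum(unmapped), " unmapped records skipped")
  keep <- which(!drop)
  if (!length(keep)) return(empty_alignments())
  seqs <- as.character(b$seq[keep])
  rows <- lapply(seq_along(keep), function(ii) {
    i <- keep[ii]
    d <- decode_record(b$pos[i], b$cigar[i], seqs[ii], flag[i])
    data.frame(read_id = b$qname[i], ref = as.character(b$rname[i]),
               ref_start = d$ref_start, ref_end = d$ref_end,
               strand = d$strand, read_start = d$read_start,
               read_end = d$read_end,
               primary = bitwAnd(flag[i], 2048L) == 0L,
               bases = d$bases, read_len = d$read_len, hap = NA_integer_)
  })
  do.call(rbind, rows)
}
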