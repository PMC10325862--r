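#' Label alignment blocks with locus regions
#'
#' Each block is labeled with the region holding its largest overlap: the
#' label is confident when at least `min_overlap_frac` of the block lies
#' inside that region, and a block straddling a native region border takes
#' the majority region's label. Blocks shorter than `min_block` stay
#' unlabeled (guards against spurious micro-alignments inside repeats).
#' Per-region overlap widths are kept so spanning-read searches can use
#' overlap semantics on merged alignments.
#'
#' @param aln alignment-block data.frame.
#' @param map a [region_map()].
#' @param min_block minimum block length in bp for labeling.
#' @param min_overlap_frac fraction of the block inside the region for a
#'   confident label.
#' @return `aln` with added columns `region` (NA when unlabeled),
#'   `region_frac`, `region_confident`, and one `ov_<region>` overlap-width
#'   column per region.
#' @export
assign_blocks <- function(aln, map, min_block = 200,
                          min_overlap_frac = 0.8) {
  regs <- map$regions
  width <- aln$ref_end - aln$ref_start + 1
  ov <- sapply(seq_len(nrow(regs)), function(i)
    pmax(0, pmin(aln$ref_end, regs$end[i]) -
           pmax(aln$ref_start, regs$start[i]) + 1))
  if (nrow(aln) == 1L) ov <- matrix(ov, nrow = 1)
  colnames(ov) <- regs$region
  best <- max.col(ov, ties.method = "first")
  best_ov <- ov[cbind(seq_len(nrow(aln)), best)]
  labeled <- width >= min_block & best_ov > 0
  aln$region <- ifelse(labeled, regs$region[best], NA_character_)
  aln$region_frac <- ifelse(width > 0, best_ov / width, 0)
  aln$region_confident <- labeled & aln$region_frac >= min_overlap_frac
  for (i in seq_len(nrow(regs)))
    aln[[paste0("ov_", regs$region[i])]] <- ov[, i]
  aln
}

regions_adjacent <- function(map, r1, r2) {
  abs(match(r1, map$regions$region) - match(r2, map$regions$region)) == 1L
}

#' Find reads spanning two named regions
#'
#' Returns the reads that align to both regions (each with at least
#' `min_block` bp of overlap, summed over the read's blocks). For adjacent
#' region pairs such spanning is expected of native reads and the result is
#' flagged accordingly; for the non-adjacent Dup1--Dup2 pair it is the
#' rearrangement-read shortlist.
#'
#' @param aln labeled alignments from [assign_blocks()].
#' @param map a [region_map()].
#' @param regions character vector of two region names.
#' @param min_block minimum per-region overlap in bp.
#' @return alignment blocks of the qualifying reads; attribute
#'   `adjacent_pair` is TRUE when the two regions are native neighbours.
#' @export
find_spanning_reads <- function(aln, map, regions = c("Dup1", "Dup2"),
                                min_block = 200) {
  stopifnot(length(regions) == 2L)
  c1 <- paste0("ov_", regions[1]); c2 <- paste0("ov_", regions[2])
  if (!all(c(c1, c2) %in% names(aln)))
    stop("run assign_blocks() first")
  ov1 <- tapply(aln[[c1]], aln$read_id, sum)
  ov2 <- tapply(aln[[c2]], aln$read_id, sum)
  ids <- names(ov1)[ov1 >= min_block & ov2 >= min_block]
  out <- aln[aln$read_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "adjacent_pair") <- regions_adjacent(map, regions[1], regions[2])
  out
}

near_border <- function(pos, border, tol) abs(pos - border) <= tol

## which border (START/END) of `region` is the point near? NA if neither.
border_label <- function(pos, map, region, tol) {
  r <- region_row(map, region)
  ifelse(near_border(pos, r$start, tol), "START",
         ifelse(near_border(pos, r$end, tol), "END", NA_character_))
}

classify_pair <- function(b1, b2, map, end_tolerance) {
  ## b1 overlaps Dup1, b2 overlaps Dup2, adjacent in read order (b1 first)
  exit1 <- if (b1$strand == "+") b1$ref_end else b1$ref_start
  entry2 <- if (b2$strand == "+") b2$ref_start else b2$ref_end
  entry1 <- if (b1$strand == "+") b1$ref_start else b1$ref_end
  exit2 <- if (b2$strand == "+") b2$ref_end else b2$ref_start
  e1 <- border_label(exit1, map, "Dup1", end_tolerance)
  e2 <- border_label(entry2, map, "Dup2", end_tolerance)
  lab_or <- function(p, region) {
    l <- border_label(p, map, region, end_tolerance)
    if (is.na(l)) "MID" else l
  }
  sig <- paste0(lab_or(entry1, "Dup1"), "-DUP1-", lab_or(exit1, "Dup1"), "|",
                lab_or(entry2, "Dup2"), "-DUP2-", lab_or(exit2, "Dup2"))
  opp <- b1$strand != b2$strand
  colinear <- b1$strand == b2$strand &&
    ((b1$strand == "+" && b2$ref_start > b1$ref_start) ||
       (b1$strand == "-" && b2$ref_start < b1$ref_start))
  if (is.na(e1) || is.na(e2)) {
    if (colinear) return(list(type = "native", signature = sig))
    return(list(type = "unclassified", signature = sig,
                reason = "junction-side endpoint far from region border"))
  }
  if (opp && e1 == "END" && e2 == "END")
    return(list(type = "A", signature = sig))
  if (opp && e1 == "START" && e2 == "START")
    return(list(type = "B", signature = sig))
  if (colinear) return(list(type = "native", signature = sig))
  list(type = "unclassified", signature = sig,
       reason = "orientation pattern matches no junction")
}

#' Classify the junction(s) a read spans
#'
#' Walks the read's blocks in read order and classifies every adjacent
#' Dup1/Dup2 block pair by the orientation grammar of the carrier
#' junctions: a forward Dup1 block exiting at Dup1's end joined to a
#' reverse Dup2 block at Dup2's end (signature
#' `START-DUP1-END|END-DUP2-START`) is junction A (Dup1 + inverted Dup2);
#' the mirrored `END-DUP1-START|START-DUP2-END` pattern is junction B
#' (inverted Dup1 + Dup2). A colinear same-strand traversal (one merged
#' block, or ref-monotone blocks through Int) is native. Classification is
#' invariant under reversing the read. Junction-side endpoints further than
#' `end_tolerance` from a region border leave the pair unclassified.
#'
#' @param blocks labeled alignment blocks of one read ([assign_blocks()]).
#' @param map a [region_map()].
#' @param end_tolerance tolerance in bp for matching block endpoints to
#'   region borders (absorbs alignment clipping jitter).
#' @return data.frame of calls: `read_id`, `type`
#'   (`A`/`B`/`native`/`unclassified`), `signature`, `reason`.
#' @export
classify_junction <- function(blocks, map, end_tolerance = 100) {
  blocks <- blocks[order(blocks$read_start), , drop = FALSE]
  n <- nrow(blocks)
  min_ov <- 1
  has1 <- blocks$ov_Dup1 > 0
  has2 <- blocks$ov_Dup2 > 0
  calls <- list()
  ## single colinear block covering both regions: native traversal
  both <- which(has1 & has2)
  for (i in both)
    calls[[length(calls) + 1L]] <-
      data.frame(read_id = blocks$read_id[1], type = "native",
                 signature = "DUP1-INT-DUP2 colinear", reason = NA_character_)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      b1 <- blocks[i, ]; b2 <- blocks[i + 1L, ]
      pair <- NULL
      if (b1$ov_Dup1 >= min_ov && !has2[i] && b2$ov_Dup2 >= min_ov && !has1[i + 1L]) {
        pair <- classify_pair(b1, b2, map, end_tolerance)
      } else if (b1$ov_Dup2 >= min_ov && !has1[i] && b2$ov_Dup1 >= min_ov && !has2[i + 1L]) {
        ## reverse the read so Dup1 comes first: flip order and strands
        rb1 <- b2; rb2 <- b1
        rb1$strand <- if (b2$strand == "+") "-" else "+"
        rb2$strand <- if (b1$strand == "+") "-" else "+"
        pair <- classify_pair(rb1, rb2, map, end_tolerance)
      }
      if (!is.null(pair))
        calls[[length(calls) + 1L]] <-
          data.frame(read_id = blocks$read_id[1], type = pair$type,
                     signature = pair$signature,
                     reason = if (is.null(pair$reason)) NA_character_
                              else pair$reason)
    }
  }
  if (!length(calls))
    return(data.frame(read_id = character(0), type = character(0),
                      signature = character(0), reason = character(0)))
  do.call(rbind, calls)
}

#' Classify junctions for all Dup1--Dup2 spanning reads
#'
#' @param aln labeled alignments ([assign_blocks()]); unlabeled input is
#'   labeled on the fly.
#' @param map a [region_map()].
#' @param end_tolerance see [classify_junction()].
#' @param min_block see [find_spanning_reads()].
#' @return data.frame of junction calls, one row per classified block pair.
#' @export
classify_junctions <- function(aln, map, end_tolerance = 100,
                               min_block = 200) {
  if (!"region" %in% names(aln)) aln <- assign_blocks(aln, map, min_block)
  sp <- find_spanning_reads(aln, map, c("Dup1", "Dup2"), min_block)
  if (!nrow(sp))
    return(data.frame(read_id = character(0), type = character(0),
                      signature = character(0), reason = character(0)))
  out <- lapply(split(sp, sp$read_id), classify_junction, map = map,
                end_tolerance = end_tolerance)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate junction support per type
#'
#' Counts distinct reads supporting each junction type; feeds
#' [classify_carrier()].
#'
#' @param calls data.frame from [classify_junctions()].
#' @return named integer vector with elements `A`, `B`, `native`,
#'   `unclassified`.
#' @export
junction_support_table <- function(calls) {
  out <- c(A = 0L, B = 0L, native = 0L, unclassified = 0L)
  if (nrow(calls)) {
    u <- unique(calls[, c("read_id", "type")])
    tb <- table(u$type)
    out[names(tb)] <- as.integer(tb)
  }
  out
}
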