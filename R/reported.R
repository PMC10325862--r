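#' Published Silkie long-read phasing tallies
#'
#' Per-duplicated-region bookkeeping of the published Silkie long-read
#' phasing of the locus: candidate heterozygous sites shortlisted by the
#' >= 10-reads-per-allele rule, haplotype-defining sites retained by the
#' pair-linkage extension, the denominators the ~1% density was quoted
#' against, and the seed sites the extension started from.
#'
#' @return data.frame with columns `region`, `length_bp`,
#'   `candidate_sites`, `defining_sites`, `seed_site`.
#' @export
silkie_phasing_counts <- function() {
  utils::read.table(system.file("extdata", "silkie_phasing_site_counts.tsv",
                                package = "fmphase"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Summarize phasing bookkeeping across regions
#'
#' Totals candidate and haplotype-defining sites over the duplicated
#' regions and computes the candidate-site density per bp — the
#' consistency arithmetic behind "49 of 2,988 sites sufficed to span both
#' regions".
#'
#' @param counts data.frame as returned by [silkie_phasing_counts()] (or
#'   an equivalent tally of a synthetic run).
#' @return list: `candidate_total`, `defining_total`, `density` (named
#'   per-region candidate density), `per_region` (the input).
#' @export
phasing_site_summary <- function(counts = silkie_phasing_counts()) {
  list(candidate_total = sum(counts$candidate_sites),
       defining_total = sum(counts$defining_sites),
       density = stats::setNames(counts$candidate_sites / counts$length_bp,
                                 counts$region),
       per_region = counts)
}

#' Construct synthetic junction-spanning read alignments
#'
#' Builds alignment blocks of idealized reads spanning the two
#' carrier-specific junctions at a region map's coordinates, for testing
#' the junction classifier against known geometry (e.g. the published
#' 3 junction-A / 2 junction-B read split, reproduced here with synthetic
#' stand-in reads at the real GRCg6a breakpoints — the original PacBio
#' reads require their multi-hundred-GB accession).
#'
#' @param map a [region_map()].
#' @param n_a,n_b number of junction-A and junction-B reads.
#' @param arm aligned bases on each side of the junction.
#' @return alignment-block data.frame compatible with [assign_blocks()].
#' @export
synthetic_junction_reads <- function(map, n_a = 3, n_b = 2, arm = 5000) {
  d1 <- region_row(map, "Dup1"); d2 <- region_row(map, "Dup2")
  rows <- list()
  add <- function(id, b1, b2) {
    rows[[length(rows) + 1L]] <<- cbind(read_id = id,
                                        ref = map$chrom,
                                        rbind(b1, b2),
                                        bases = NA_character_,
                                        read_len = 2 * arm, hap = NA_integer_)
  }
  for (i in seq_len(n_a)) {
    ## forward Dup1 arm ending at Dup1.END, then inverted Dup2 arm ending
    ## at Dup2.END: START-DUP1-END | END-DUP2-START
    b1 <- data.frame(ref_start = d1$end - arm + 1, ref_end = d1$end,
                     strand = "+", read_start = 1, read_end = arm,
                     primary = TRUE)
    b2 <- data.frame(ref_start = d2$end - arm + 1, ref_end = d2$end,
                     strand = "-", read_start = arm + 1, read_end = 2 * arm,
                     primary = FALSE)
    add(sprintf("junctionA_read%d", i), b1, b2)
  }
  for (i in seq_len(n_b)) {
    ## inverted Dup1 arm at Dup1.START, then forward Dup2 arm from
    ## Dup2.START: END-DUP1-START | START-DUP2-END
    b1 <- data.frame(ref_start = d1$start, ref_end = d1$start + arm - 1,
                     strand = "-", read_start = 1, read_end = arm,
                     primary = TRUE)
    b2 <- data.frame(ref_start = d2$start, ref_end = d2$start + arm - 1,
                     strand = "+", read_start = arm + 1, read_end = 2 * arm,
                     primary = FALSE)
    add(sprintf("junctionB_read%d", i), b1, b2)
  }
  out <- do.call(rbind, rows)
  out[, c("read_id", "ref", "ref_start", "ref_end", "strand", "read_start",
          "read_end", "primary", "bases", "read_len", "hap")]
}
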