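## VCF / population-map / BED interchange for haplotype panels.

#' Write a haplotype panel as phased VCF 4.2
#'
#' Diploid samples with phased `GT` (`0|1` style) fields; written through
#' vcfR (gzip-compressed when the path ends in `.gz`).
#'
#' @param panel a [hap_panel()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return the path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_panel_vcf <- function(panel, path) {
  S <- ncol(panel$geno)
  k <- nrow(panel$geno) / 2
  fix <- cbind(CHROM = rep(panel$chrom, S),
               POS = format(panel$pos, scientific = FALSE, trim = TRUE),
               ID = rep(".", S), REF = rep("A", S), ALT = rep("T", S),
               QUAL = rep(".", S), FILTER = rep("PASS", S),
               INFO = rep(".", S))
  gt <- matrix("", nrow = S, ncol = k + 1)
  gt[, 1] <- "GT"
  for (i in seq_len(k))
    gt[, i + 1] <- paste0(panel$geno[2 * i - 1, ], "|", panel$geno[2 * i, ])
  colnames(gt) <- c("FORMAT", panel$samples$sample)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", panel$chrom, ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(obj, file = path)
  } else {
    ## vcfR::write.vcf always gzips; decompress for a plain .vcf path
    tmp <- paste0(path, ".gz")
    vcfR::write.vcf(obj, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic phased records only; the population map supplies per-sample
#' labels.
#'
#' @param path VCF path (plain or gzipped).
#' @param popmap data.frame (`sample`, `pop`) or path to a two-column TSV.
#' @return a [hap_panel()].
#' @export
read_panel_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_pop_map(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  pos <- as.numeric(v@fix[, "POS"])
  chrom <- v@fix[1, "CHROM"]
  gtf <- sub(":.*$", "", gt)  # GT is the leading FORMAT field
  if (any(!grepl("^[01]\\|[01]$", gtf)))
    stop("panel VCF must be phased and biallelic (GT like 0|1)")
  a1 <- matrix(as.integer(substr(gtf, 1, 1)), nrow = nrow(gtf))
  a2 <- matrix(as.integer(substr(gtf, 3, 3)), nrow = nrow(gtf))
  geno <- matrix(0L, nrow = 2 * length(samples), ncol = length(pos))
  for (i in seq_along(samples)) {
    geno[2 * i - 1, ] <- a1[, i]
    geno[2 * i, ] <- a2[, i]
  }
  pops <- popmap$pop[match(samples, popmap$sample)]
  if (anyNA(pops)) stop("samples missing from population map")
  hap_panel(geno, pos, chrom = chrom,
            hap_pop = rep(pops, each = 2),
            samples = data.frame(sample = samples, pop = pops))
}

#' Read / write a population map (sample TAB population)
#' @param popmap data.frame with columns `sample`, `pop`.
#' @param path TSV path.
#' @return `write_pop_map` returns the path invisibly; `read_pop_map`
#'   the data.frame.
#' @export
write_pop_map <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "pop")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pop_map
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "pop"),
                          stringsAsFactors = FALSE)
  df
}

#' Read / write interval masks as BED
#'
#' Masks are held internally as 1-based inclusive intervals; on disk they
#' follow the BED convention (0-based half-open).
#'
#' @param mask data.frame with `start`, `end` (1-based inclusive).
#' @param path BED path.
#' @param chrom chromosome name for the BED records.
#' @return `write_mask_bed` returns the path invisibly; `read_mask_bed`
#'   the mask data.frame.
#' @export
write_mask_bed <- function(mask, path, chrom = "1") {
  bed <- data.frame(chrom = chrom,
                    start = format(mask$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(mask$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_bed
#' @export
read_mask_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(data.frame(start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  data.frame(start = df[[2]] + 1, end = df[[3]])
}

#' Write phased duplicated-region haplotypes as a PS-tagged VCF
#'
#' One diploid "sample" whose two phased alleles are the two copy-specific
#' haplotypes of each duplicated region; the phase-set (PS) tag is the
#' region's seed site.
#'
#' @param phased_list list of [extend_haplotypes()] results.
#' @param chrom chromosome name.
#' @param path output path.
#' @param sample_id sample column name.
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(phased_list, chrom, path,
                             sample_id = "haplotypes") {
  rows <- list()
  for (ph in phased_list) {
    ch <- ph$sites
    rows[[length(rows) + 1L]] <-
      data.frame(pos = ch$pos, ref = ch$hapA, alt = ch$hapB,
                 ps = ph$seed)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$pos), ]
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chrom, ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample_id),
             paste0(chrom, "\t", format(df$pos, scientific = FALSE,
                                        trim = TRUE),
                    "\t.\t", df$ref, "\t", df$alt,
                    "\t.\tPASS\t.\tGT:PS\t0|1:",
                    format(df$ps, scientific = FALSE, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}
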