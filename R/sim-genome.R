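## Sequence helpers ---------------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

#' Random reference genome over a region map span
#'
#' Uniform-composition random DNA covering the map span; position 1 of the
#' returned string corresponds to the map's first reference coordinate.
#'
#' @param map a [region_map()].
#' @return a single character string of length `diff(map_span(map)) + 1`.
#' @export
random_genome <- function(map) {
  sp <- map_span(map)
  paste(sample(c("A", "C", "G", "T"), sp[2] - sp[1] + 1, replace = TRUE),
        collapse = "")
}

genome_sub <- function(genome, map, start, end) {
  off <- map_span(map)[1] - 1
  substr(genome, start - off, end - off)
}

## Locus haplotype ----------------------------------------------------------

#' Build the sequence of one locus haplotype
#'
#' Concatenates the arrangement's segments (reverse-complementing inverted
#' ones) into the haplotype ("sample") sequence, together with a piecewise
#' monotone projection map from sample coordinates to signed reference
#' intervals — the truth lift-over used to place simulated reads.
#'
#' @param map a [region_map()].
#' @param a an [arrangement()].
#' @param genome reference sequence from [random_genome()] (or any string
#'   covering the map span).
#' @return object of class `locus_haplotype`: list with `seq` (character),
#'   `projection` (data.frame: `sample_start`, `sample_end`, `ref_start`,
#'   `ref_end`, `strand`, `region`, `copy`), `arrangement`, `map`.
#' @export
build_haplotype_sequence <- function(map, a, genome) {
  seg <- a$segments
  unknown <- setdiff(seg$region, map$regions$region)
  if (length(unknown))
    stop("arrangement references regions absent from map: ",
         paste(unknown, collapse = ", "))
  sp <- map_span(map)
  if (nchar(genome) < sp[2] - sp[1] + 1)
    stop("genome does not cover the region-map span")
  pieces <- character(nrow(seg))
  proj <- vector("list", nrow(seg))
  copy_counter <- integer(0)
  pos <- 1
  for (i in seq_len(nrow(seg))) {
    r <- region_row(map, seg$region[i])
    s <- genome_sub(genome, map, r$start, r$end)
    if (seg$orient[i] == "-") s <- revcomp(s)
    pieces[i] <- s
    len <- nchar(s)
    cc <- copy_counter[seg$region[i]]
    cc <- if (is.na(cc) || is.null(cc)) 1L else cc + 1L
    copy_counter[seg$region[i]] <- cc
    proj[[i]] <- data.frame(sample_start = pos, sample_end = pos + len - 1,
                            ref_start = r$start, ref_end = r$end,
                            strand = seg$orient[i],
                            region = seg$region[i], copy = cc)
    pos <- pos + len
  }
  structure(list(seq = paste(pieces, collapse = ""),
                 projection = do.call(rbind, proj),
                 arrangement = a, map = map),
            class = "locus_haplotype")
}

#' @export
print.locus_haplotype <- function(x, ...) {
  cat("<locus_haplotype> *", x$arrangement$name, ", ",
      format(nchar(x$seq), big.mark = ","), " bp, ",
      nrow(x$projection), " projection blocks\n", sep = "")
  invisible(x)
}

#' Project sample positions to reference positions
#'
#' @param hap a [build_haplotype_sequence()] result.
#' @param pos vector of 1-based sample coordinates.
#' @return data.frame with `sample_pos`, `ref_pos`, `strand`, `region`,
#'   `copy`.
#' @export
project_to_ref <- function(hap, pos) {
  p <- hap$projection
  blk <- findInterval(pos, p$sample_start)
  if (any(blk < 1 | pos > p$sample_end[blk]))
    stop("sample position outside haplotype")
  ref <- ifelse(p$strand[blk] == "+",
                p$ref_start[blk] + (pos - p$sample_start[blk]),
                p$ref_end[blk] - (pos - p$sample_start[blk]))
  data.frame(sample_pos = pos, ref_pos = ref, strand = p$strand[blk],
             region = p$region[blk], copy = p$copy[blk])
}

#' All sample positions mapping to a reference position
#'
#' Inverse projection; duplicated regions return one sample position per
#' copy.
#'
#' @inheritParams project_to_ref
#' @param ref_pos a single 1-based reference coordinate.
#' @return data.frame with `sample_pos`, `strand`, `region`, `copy`.
#' @export
ref_to_sample <- function(hap, ref_pos) {
  stopifnot(length(ref_pos) == 1L)
  p <- hap$projection
  hit <- which(p$ref_start <= ref_pos & ref_pos <= p$ref_end)
  sp <- ifelse(p$strand[hit] == "+",
               p$sample_start[hit] + (ref_pos - p$ref_start[hit]),
               p$sample_start[hit] + (p$ref_end[hit] - ref_pos))
  data.frame(sample_pos = sp, strand = p$strand[hit],
             region = p$region[hit], copy = p$copy[hit])
}

## Het-site planting --------------------------------------------------------

#' Plant heterozygous sites into a diploid pair of locus haplotypes
#'
#' Two classes of sites are planted. Inside each duplicated region, sites
#' are drawn at `het_density_dup` and carry two ancestral allele classes:
#' copy 1 of the region carries class 1, copy 2 carries class 2 (shared by
#' both chromosomes when both carry the duplication — the duplication arose
#' once), and a single-copy (`*N`) chromosome carries the ancestral-like
#' class 2. The two copies of a duplicated region therefore differ at every
#' planted site, which is exactly what makes copy-specific haplotypes
#' separable by read-backed phasing. Outside the duplicated regions,
#' ordinary chromosome-level heterozygous sites are planted at
#' `het_density_bg` (chromosome 1 vs chromosome 2).
#'
#' @param cfg a [sim_config()].
#' @param dip list of the two [build_haplotype_sequence()] haplotypes.
#' @param genome the reference string the haplotypes were built from.
#' @return truth list: `sites` (data.frame `pos`, `region`, `type`, `ref`,
#'   `class1`, `class2`), `assignment` (data.frame `chrom`, `region`,
#'   `copy`, `class` for duplicated-region instances).
#' @export
plant_het_sites <- function(cfg, dip, genome) {
  map <- cfg$map
  dup_regions <- intersect(c("Dup1", "Dup2"), map$regions$region)
  bases <- c("A", "C", "G", "T")
  draw_sites <- function(region, density, type) {
    r <- region_row(map, region)
    L <- r$end - r$start + 1
    n <- stats::rbinom(1, L, density)
    if (n == 0L)
      return(NULL)
    pos <- sort(sample.int(L, n)) + r$start - 1
    ref <- substring(genome_sub(genome, map, r$start, r$end),
                     pos - r$start + 1, pos - r$start + 1)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    data.frame(pos = pos, region = region, type = type, ref = ref,
               class1 = ifelse(swap, alt, ref),
               class2 = ifelse(swap, ref, alt))
  }
  dup_sites <- do.call(rbind, lapply(dup_regions, function(r)
    draw_sites(r, cfg$het_density_dup, "dup")))
  bg_regions <- setdiff(map$regions$region, dup_regions)
  bg_sites <- do.call(rbind, lapply(bg_regions, function(r)
    draw_sites(r, cfg$het_density_bg, "bg")))
  sites <- rbind(dup_sites, bg_sites)
  if (!is.null(sites)) {
    sites <- sites[order(sites$pos), ]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(pos = numeric(0), region = character(0),
                        type = character(0), ref = character(0),
                        class1 = character(0), class2 = character(0))
  }

  ## allele-class assignment per duplicated-region instance
  assignment <- do.call(rbind, lapply(dup_regions, function(r) {
    k <- vapply(dip, function(h) sum(h$projection$region == r), integer(1))
    do.call(rbind, lapply(1:2, function(ch) {
      if (k[ch] == 0L) return(NULL)
      if (k[ch] >= 2L) {
        if (k[ch] > 2L)
          warning("more than two copies of ", r, "; extra copies get class 2")
        cls <- pmin(seq_len(k[ch]), 2L)
      } else {
        cls <- if (k[3 - ch] >= 2L) 2L else ch
      }
      data.frame(chrom = ch, region = r, copy = seq_len(k[ch]), class = cls)
    }))
  }))
  if (is.null(assignment))
    assignment <- data.frame(chrom = integer(0), region = character(0),
                             copy = integer(0), class = integer(0))
  list(sites = sites, assignment = assignment)
}

#' Write planted alleles into the haplotype sequences
#'
#' @param dip list of two [build_haplotype_sequence()] haplotypes.
#' @param truth result of [plant_het_sites()].
#' @return the diploid list with mutated `seq` fields.
#' @export
apply_het_sites <- function(dip, truth) {
  sites <- truth$sites
  for (ch in 1:2) {
    hap <- dip[[ch]]
    chars <- strsplit(hap$seq, "", fixed = TRUE)[[1]]
    p <- hap$projection
    for (bi in seq_len(nrow(p))) {
      blk <- p[bi, ]
      in_blk <- sites$region == blk$region
      if (!any(in_blk)) next
      ss <- sites[in_blk, ]
      if (blk$region %in% unique(truth$assignment$region)) {
        cls <- truth$assignment$class[truth$assignment$chrom == ch &
                                        truth$assignment$region == blk$region &
                                        truth$assignment$copy == blk$copy]
        allele <- if (cls == 1L) ss$class1 else ss$class2
      } else {
        allele <- if (ch == 1L) ss$class1 else ss$class2
      }
      sp <- if (blk$strand == "+")
        blk$sample_start + (ss$pos - blk$ref_start)
      else
        blk$sample_start + (blk$ref_end - ss$pos)
      chars[sp] <- if (blk$strand == "+") allele else comp_base(allele)
    }
    hap$seq <- paste(chars, collapse = "")
    dip[[ch]] <- hap
  }
  dip
}

#' True alleles carried by each duplicated-region instance
#'
#' Expands the truth assignment into one row per (chromosome, copy, site).
#'
#' @param truth result of [plant_het_sites()].
#' @return data.frame `chrom`, `region`, `copy`, `class`, `pos`, `allele`.
#' @export
truth_instance_alleles <- function(truth) {
  a <- truth$assignment
  out <- lapply(seq_len(nrow(a)), function(i) {
    ss <- truth$sites[truth$sites$region == a$region[i], ]
    if (!nrow(ss)) return(NULL)
    data.frame(chrom = a$chrom[i], region = a$region[i], copy = a$copy[i],
               class = a$class[i], pos = ss$pos,
               allele = if (a$class[i] == 1L) ss$class1 else ss$class2)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = integer(0), region = character(0),
                      copy = integer(0), class = integer(0),
                      pos = numeric(0), allele = character(0)))
  do.call(rbind, out)
}
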