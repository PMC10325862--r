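## Read-level simulation: long reads with junction-split alignments,
## short-read depth tracks, and SAM emission against the un-rearranged
## reference. Alignments are represented throughout the package as a
## data.frame of alignment blocks:
##   read_id, ref, ref_start, ref_end, strand, read_start, read_end,
##   primary, bases (reference-forward aligned bases), read_len, hap
## 1-based inclusive coordinates; read_start/read_end are offsets in the
## original read orientation.

empty_alignments <- function() {
  data.frame(read_id = character(0), ref = character(0),
             ref_start = numeric(0), ref_end = numeric(0),
             strand = character(0), read_start = numeric(0),
             read_end = numeric(0), primary = logical(0),
             bases = character(0), read_len = numeric(0), hap = integer(0))
}

## Split a sample-coordinate interval [s, e] of one haplotype into merged,
## aligner-like reference blocks: colinear projection blocks that are
## reference-contiguous are merged (a read crossing a native region border
## aligns as one block; only true rearrangement junctions split it).
sample_interval_blocks <- function(hap, s, e) {
  p <- hap$projection
  from <- findInterval(s, p$sample_start)
  to <- findInterval(e, p$sample_start)
  idx <- from:to
  runs <- list()
  run_start <- idx[1]
  prev <- idx[1]
  if (length(idx) > 1L) {
    for (i in idx[-1]) {
      contiguous <- p$strand[i] == p$strand[prev] &&
        ((p$strand[i] == "+" && p$ref_start[i] == p$ref_end[prev] + 1) ||
           (p$strand[i] == "-" && p$ref_end[i] == p$ref_start[prev] - 1))
      if (!contiguous) {
        runs[[length(runs) + 1L]] <- c(run_start, prev)
        run_start <- i
      }
      prev <- i
    }
  }
  runs[[length(runs) + 1L]] <- c(run_start, prev)
  out <- lapply(runs, function(r) {
    f <- r[1]
    bs <- max(s, p$sample_start[f])
    be <- min(e, p$sample_end[r[2]])
    if (p$strand[f] == "+") {
      rs <- p$ref_start[f] + (bs - p$sample_start[f])
      re <- rs + (be - bs)
    } else {
      re <- p$ref_end[f] - (bs - p$sample_start[f])
      rs <- re - (be - bs)
    }
    data.frame(sample_start = bs, sample_end = be, ref_start = rs,
               ref_end = re, strand = p$strand[f])
  })
  do.call(rbind, out)
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  ks <- stats::rbinom(length(seqs), lens, error_rate)
  for (i in which(ks > 0L)) {
    pos <- sample.int(lens[i], ks[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ## substitute by a uniform non-identity shift in base space
    idx <- match(ch[pos], bases)
    shift <- sample.int(3L, ks[i], replace = TRUE)
    ch[pos] <- bases[((idx - 1L + shift) %% 4L) + 1L]
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate long reads from a diploid locus sample
#'
#' Reads are drawn uniformly along each chromosome haplotype with log-normal
#' lengths truncated at the haplotype ends, i.i.d. per-base substitution
#' errors, and are decomposed into reference alignment blocks via the
#' haplotype projection map: reads wholly inside one segment copy give a
#' single block; reads crossing a rearrangement junction split into blocks
#' with the correct strands (e.g. a read over the Dup1.END--Dup2.END
#' junction of `*Fm_2` yields a forward block ending at Dup1's end plus a
#' reverse block ending at Dup2's end).
#'
#' @param cfg a [sim_config()].
#' @param dip diploid list of mutated haplotypes ([apply_het_sites()]).
#' @param sample_id sample name used in read ids.
#' @return list: `alignments` (block data.frame, also the per-read truth),
#'   `reads` (data.frame `read_id`, `hap`, `sample_start`, `sample_end`,
#'   `read_len`, `seq`).
#' @export
simulate_long_reads <- function(cfg, dip, sample_id = "S1") {
  lr <- cfg$long_read
  aln <- list()
  reads <- list()
  for (ch in 1:2) {
    hap <- dip[[ch]]
    L <- nchar(hap$seq)
    target <- L * lr$depth / 2
    starts <- integer(0); lens <- integer(0)
    while (sum(lens) < target) {
      n0 <- max(10L, ceiling((target - sum(lens)) / exp(lr$meanlog)))
      st <- sample.int(L, n0, replace = TRUE)
      ln <- pmax(lr$min_len, round(stats::rlnorm(n0, lr$meanlog, lr$sdlog)))
      ln <- pmin(ln, L - st + 1)
      starts <- c(starts, st); lens <- c(lens, ln)
      cum <- cumsum(lens)
      if (any(cum >= target)) {
        k <- which(cum >= target)[1]
        starts <- starts[seq_len(k)]; lens <- lens[seq_len(k)]
        break
      }
    }
    ends <- starts + lens - 1
    ids <- sprintf("%s_h%d_r%05d", sample_id, ch, seq_along(starts))
    seqs <- substring(hap$seq, starts, ends)
    seqs <- apply_substitution_errors(seqs, lr$error_rate)
    blocks <- lapply(seq_along(starts), function(i) {
      b <- sample_interval_blocks(hap, starts[i], ends[i])
      rs <- b$sample_start - starts[i] + 1
      re <- b$sample_end - starts[i] + 1
      bas <- substring(seqs[i], rs, re)
      inv <- b$strand == "-"
      if (any(inv)) bas[inv] <- revcomp(bas[inv])
      data.frame(read_id = ids[i], ref = hap$map$chrom,
                 ref_start = b$ref_start, ref_end = b$ref_end,
                 strand = b$strand, read_start = rs, read_end = re,
                 primary = seq_len(nrow(b)) == which.max(re - rs),
                 bases = bas, read_len = lens[i], hap = ch)
    })
    aln[[ch]] <- do.call(rbind, blocks)
    reads[[ch]] <- data.frame(read_id = ids, hap = ch,
                              sample_start = starts, sample_end = ends,
                              read_len = lens, seq = seqs)
  }
  list(alignments = do.call(rbind, aln), reads = do.call(rbind, reads))
}

#' Simulate a short-read depth track (and read placements)
#'
#' Paired-end fragments are drawn uniformly along each chromosome
#' haplotype; a read crossing a rearrangement junction aligns as its
#' within-segment blocks, each soft-clipped at the breakpoint (as a
#' mapper reports a clipped primary plus a seedable supplementary;
#' fragments shorter than a seed, < 20 bp, on one side are dropped on
#' that side). The per-base depth track over the reference span has
#' expected relative depth over a duplicated region equal to the summed
#' carrier copy number / 2 (1.5x for an Fm/N heterozygote, 2x for an Fm
#' homozygote).
#'
#' @inheritParams simulate_long_reads
#' @return list: `depth` (integer vector over the map span), `offset`
#'   (reference coordinate of `depth[1]`), `reads` (alignment-block
#'   data.frame without sequences).
#' @export
simulate_short_read_depth <- function(cfg, dip, sample_id = "S1") {
  sr <- cfg$short_read
  map <- dip[[1]]$map
  sp <- map_span(map)
  blocks <- list()
  for (ch in 1:2) {
    hap <- dip[[ch]]
    L <- nchar(hap$seq)
    n_frag <- round(L * sr$depth / 2 / (2 * sr$length))
    fs <- sample.int(L, n_frag, replace = TRUE)
    ins <- pmax(sr$length, round(stats::rnorm(n_frag, sr$insert, sr$insert_sd)))
    fe <- pmin(fs + ins - 1, L)
    r1s <- fs; r1e <- pmin(fs + sr$length - 1, L)
    r2s <- pmax(fe - sr$length + 1, 1); r2e <- fe
    st <- c(r1s, r2s); en <- c(r1e, r2e)
    mate <- rep(1:2, each = n_frag)
    ids <- sprintf("%s_h%d_f%06d/%d", sample_id, ch,
                   rep(seq_len(n_frag), 2), mate)
    ## vectorized fast path: reads wholly inside one projection block
    p <- hap$projection
    from <- findInterval(st, p$sample_start)
    to <- findInterval(en, p$sample_start)
    inside <- from == to
    rs <- re <- numeric(length(st))
    strand <- character(length(st))
    read_start <- st * 0 + 1
    read_end <- en - st + 1
    f <- from[inside]
    plus <- p$strand[f] == "+"
    rs[inside] <- ifelse(plus, p$ref_start[f] + (st[inside] - p$sample_start[f]),
                         p$ref_end[f] - (en[inside] - p$sample_start[f]))
    re[inside] <- rs[inside] + (en[inside] - st[inside])
    strand[inside] <- p$strand[f]
    extra <- list()
    for (i in which(!inside)) {
      b <- sample_interval_blocks(hap, st[i], en[i])
      b <- b[b$sample_end - b$sample_start + 1 >= 20, , drop = FALSE]
      if (!nrow(b)) { rs[i] <- NA; next }
      j <- which.max(b$sample_end - b$sample_start)
      rs[i] <- b$ref_start[j]; re[i] <- b$ref_end[j]
      strand[i] <- b$strand[j]
      read_start[i] <- b$sample_start[j] - st[i] + 1
      read_end[i] <- b$sample_end[j] - st[i] + 1
      for (j2 in setdiff(seq_len(nrow(b)), j))
        extra[[length(extra) + 1L]] <-
          data.frame(read_id = ids[i], ref = map$chrom,
                     ref_start = b$ref_start[j2], ref_end = b$ref_end[j2],
                     strand = b$strand[j2],
                     read_start = b$sample_start[j2] - st[i] + 1,
                     read_end = b$sample_end[j2] - st[i] + 1,
                     primary = FALSE, bases = NA_character_,
                     read_len = en[i] - st[i] + 1, hap = ch)
    }
    main <- data.frame(read_id = ids, ref = map$chrom,
                       ref_start = rs, ref_end = re, strand = strand,
                       read_start = read_start, read_end = read_end,
                       primary = TRUE, bases = NA_character_,
                       read_len = en - st + 1, hap = ch)
    main <- main[!is.na(main$ref_start), , drop = FALSE]
    blocks[[ch]] <- rbind(main, do.call(rbind, extra))
  }
  reads <- do.call(rbind, blocks)
  cov <- IRanges::coverage(IRanges::IRanges(reads$ref_start, reads$ref_end),
                           width = sp[2])
  depth <- as.integer(cov)[sp[1]:sp[2]]
  list(depth = depth, offset = sp[1], reads = reads)
}

#' Simulate a complete diploid locus sample
#'
#' Orchestrates the generator under a single seed: reference genome,
#' diploid haplotype construction, het-site planting, long reads, and a
#' short-read depth track. Re-running with the same configuration
#' reproduces identical output.
#'
#' @param cfg a [sim_config()].
#' @param sample_id sample name.
#' @param long,short logical switches for the two read layers.
#' @return list with `config`, `genome`, `dip` (mutated haplotypes),
#'   `truth` (planted sites, instance assignment, breakpoints, novel
#'   adjacencies), `long` ([simulate_long_reads()] output), `short`
#'   ([simulate_short_read_depth()] output).
#' @export
simulate_locus_sample <- function(cfg, sample_id = "S1", long = TRUE,
                                  short = TRUE) {
  set.seed(cfg$seed)
  genome <- random_genome(cfg$map)
  dip <- lapply(cfg$arrangements, function(a)
    build_haplotype_sequence(cfg$map, a, genome))
  truth <- plant_het_sites(cfg, dip, genome)
  dip <- apply_het_sites(dip, truth)
  dup_regions <- intersect(c("Dup1", "Dup2"), cfg$map$regions$region)
  truth$breakpoints <- do.call(rbind, lapply(dup_regions, function(r) {
    rr <- region_row(cfg$map, r)
    data.frame(region = r, rise = rr$start, fall = rr$end + 1)
  }))
  truth$adjacencies <- unique(rbind(
    enumerate_adjacencies(cfg$arrangements[[1]]),
    enumerate_adjacencies(cfg$arrangements[[2]])))
  out <- list(config = cfg, genome = genome, dip = dip, truth = truth,
              sample_id = sample_id)
  if (long) out$long <- simulate_long_reads(cfg, dip, sample_id)
  if (short) out$short <- simulate_short_read_depth(cfg, dip, sample_id)
  out
}
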