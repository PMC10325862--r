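## Read-backed haplotype extension across the duplicated regions.
##
## The two copies of each duplicated region co-align to the same reference
## interval, so they cannot be separated by position; they separate through
## allele linkage: candidate heterozygous sites are called from long-read
## pileups, each alignment pass is labeled by the base it carries at each
## site, co-occurrence of bases at site pairs is counted in a 4x4 matrix,
## and haplotypes are extended outward from a seed site by accepting the
## nearest site whose pair matrix cleanly separates the two chains.
##
## The unit of labeling is an alignment pass (one alignment block), not a
## read: a read traversing the whole inverted Dup2 copy of a carrier
## crosses Dup1's reference interval twice, once per copy, carrying
## different alleles on each pass.

BASES <- c("A", "C", "G", "T")

#' Pileup base counts over an interval
#'
#' Counts reads supporting each of the four nucleotide bases at every
#' position of the interval from the alignment blocks (substitution-only
#' alignments; ambiguous bases are excluded from base counts but kept in
#' depth). Zero-coverage positions are emitted with zero counts.
#'
#' @param aln alignment-block data.frame with `bases`.
#' @param interval numeric `c(from, to)` reference interval.
#' @return data.frame `pos`, `A`, `C`, `G`, `T`, `depth`.
#' @export
pileup_counts <- function(aln, interval) {
  from <- interval[1]; to <- interval[2]
  L <- to - from + 1
  sel <- which(aln$ref_end >= from & aln$ref_start <= to &
                 !is.na(aln$bases))
  tab <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  if (length(sel)) {
    bs <- pmax(aln$ref_start[sel], from)
    be <- pmin(aln$ref_end[sel], to)
    off <- bs - aln$ref_start[sel] + 1
    subs <- substr(aln$bases[sel], off, off + (be - bs))
    ch <- strsplit(paste(subs, collapse = ""), "", fixed = TRUE)[[1]]
    pos <- sequence(be - bs + 1, from = bs)
    bi <- match(ch, BASES)
    ok <- !is.na(bi)
    idx <- (pos[ok] - from) * 4 + bi[ok]
    cnt <- tabulate(idx, nbins = 4L * L)
    tab <- matrix(cnt, ncol = 4, byrow = TRUE, dimnames = list(NULL, BASES))
  }
  cov <- IRanges::coverage(IRanges::IRanges(aln$ref_start[sel],
                                            aln$ref_end[sel]), width = to)
  depth <- as.integer(cov)[from:to]
  data.frame(pos = from:to, A = tab[, 1], C = tab[, 2], G = tab[, 3],
             T = tab[, 4], depth = depth)
}

#' Call candidate heterozygous sites from pileup counts
#'
#' A site is kept iff exactly two bases reach `min_allele_reads`; sites
#' where three or more bases reach it are excluded and reported as
#' potentially tri-allelic.
#'
#' @param counts data.frame from [pileup_counts()].
#' @param min_allele_reads minimum reads per allele (default 10).
#' @return list: `sites` (data.frame `pos`, `allele1`, `allele2`, `n1`,
#'   `n2`, alleles in lexicographic order), `triallelic` (excluded sites).
#' @export
call_het_sites <- function(counts, min_allele_reads = 10) {
  m <- as.matrix(counts[, BASES])
  pass <- m >= min_allele_reads
  nb <- rowSums(pass)
  het <- which(nb == 2L)
  tri <- which(nb >= 3L)
  sites <- do.call(rbind, lapply(het, function(i) {
    w <- which(pass[i, ])
    data.frame(pos = counts$pos[i], allele1 = BASES[w[1]],
               allele2 = BASES[w[2]], n1 = m[i, w[1]], n2 = m[i, w[2]])
  }))
  if (is.null(sites))
    sites <- data.frame(pos = numeric(0), allele1 = character(0),
                        allele2 = character(0), n1 = integer(0),
                        n2 = integer(0))
  list(sites = sites,
       triallelic = counts[tri, , drop = FALSE])
}

#' Label alignment passes by the base carried at each site
#'
#' Builds the pass-by-site base matrix underlying pair counting: every
#' alignment pass covering a site with an unambiguous call appears in
#' exactly one base set at that site.
#'
#' @param aln alignment-block data.frame with `bases`.
#' @param sites data.frame with a `pos` column (e.g. from
#'   [call_het_sites()]).
#' @return object of class `site_labels`: list with `mat` (character
#'   matrix, passes x sites, NA where not covered), `pos` (site
#'   positions), `read_id`, `block` (row index into `aln`).
#' @export
label_reads <- function(aln, sites) {
  pos <- sites$pos
  units <- which(!is.na(aln$bases))
  mat <- matrix(NA_character_, nrow = length(units), ncol = length(pos))
  if (length(units) && length(pos)) {
    h <- IRanges::findOverlaps(IRanges::IRanges(pos, pos),
                               IRanges::IRanges(aln$ref_start[units],
                                                aln$ref_end[units]))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    b <- substr(aln$bases[units[si]],
                pos[qi] - aln$ref_start[units[si]] + 1,
                pos[qi] - aln$ref_start[units[si]] + 1)
    b[!b %in% BASES] <- NA_character_
    mat[cbind(si, qi)] <- b
  }
  structure(list(mat = mat, pos = pos, read_id = aln$read_id[units],
                 block = units),
            class = "site_labels")
}

#' Read-id sets per base at one site
#'
#' @param labels a [label_reads()] result.
#' @param pos site position.
#' @return named list of read-id character vectors, one per base.
#' @export
site_read_sets <- function(labels, pos) {
  j <- match(pos, labels$pos)
  if (is.na(j)) stop("site not in labels")
  b <- labels$mat[, j]
  lapply(stats::setNames(BASES, BASES), function(x)
    unique(labels$read_id[!is.na(b) & b == x]))
}

#' Base co-occurrence matrix for a site pair
#'
#' `M[b1, b2]` counts the alignment passes carrying base `b1` at site `p`
#' and `b2` at site `q` — the 16 possible combinations of the four bases
#' at the two sites.
#'
#' @param labels a [label_reads()] result.
#' @param p,q site positions (`p != q`).
#' @return 4x4 integer matrix with dimnames A, C, G, T.
#' @export
pair_matrix <- function(labels, p, q) {
  stopifnot(p != q)
  i <- match(p, labels$pos); j <- match(q, labels$pos)
  if (is.na(i) || is.na(j)) stop("site not in labels")
  bi <- labels$mat[, i]; bj <- labels$mat[, j]
  ok <- !is.na(bi) & !is.na(bj)
  table(factor(bi[ok], levels = BASES), factor(bj[ok], levels = BASES))
}

## try to link frontier (alleles fa/fb) to site q; returns NULL or the
## accepted allele assignment with support
link_step <- function(labels, p, fa, fb, q, min_pair_reads,
                      max_noise_frac) {
  m <- pair_matrix(labels, p, q)
  rowA <- m[fa, ]; rowB <- m[fb, ]
  qa <- which.max(rowA); qb <- which.max(rowB)
  if (qa == qb) return(NULL)
  ca <- rowA[qa]; cb <- rowB[qb]
  if (ca < min_pair_reads || cb < min_pair_reads) return(NULL)
  if (any(rowA[-qa] > max_noise_frac * ca)) return(NULL)
  if (any(rowB[-qb] > max_noise_frac * cb)) return(NULL)
  list(alleleA = BASES[qa], alleleB = BASES[qb],
       supportA = as.integer(ca), supportB = as.integer(cb))
}

#' Extend the two haplotypes of a duplicated region from a seed site
#'
#' From the seed outward in both directions, the nearest candidate site
#' whose pair matrix with the current frontier cleanly separates the two
#' chains is accepted: one cell per current haplotype allele with at least
#' `min_pair_reads` passes, every other cell in those rows at most
#' `max_noise_frac` of its row's accepted cell, and distinct alleles
#' between the chains. Candidates failing the rule are skipped; when no
#' acceptable site remains before the end of the candidate list the chain
#' stops and the side is flagged broken.
#'
#' @param labels a [label_reads()] result.
#' @param het_sites data.frame from [call_het_sites()] (`sites` element).
#' @param seed_pos seed site position (must be one of the het sites).
#' @param min_pair_reads minimum passes per haplotype at each accepted
#'   step (default 5).
#' @param max_noise_frac maximum fraction of an accepted cell allowed in
#'   any other cell of its row (default 0.2).
#' @param region optional region name carried into the result.
#' @return object of class `phased_haplotypes`: list with `sites`
#'   (data.frame `pos`, `hapA`, `hapB`, `supportA`, `supportB`), `seed`,
#'   `broken_left`, `broken_right`, `region`.
#' @export
extend_haplotypes <- function(labels, het_sites, seed_pos,
                              min_pair_reads = 5, max_noise_frac = 0.2,
                              region = NA_character_) {
  srow <- het_sites[het_sites$pos == seed_pos, ]
  if (nrow(srow) != 1L)
    stop("seed site is not a called biallelic het site")
  chain <- data.frame(pos = seed_pos, hapA = srow$allele1,
                      hapB = srow$allele2,
                      supportA = srow$n1, supportB = srow$n2)
  broken <- c(left = FALSE, right = FALSE)
  for (dir in c("right", "left")) {
    cand <- if (dir == "right")
      het_sites[het_sites$pos > seed_pos, , drop = FALSE]
    else
      het_sites[het_sites$pos < seed_pos, , drop = FALSE]
    cand <- cand[order(if (dir == "right") cand$pos else -cand$pos), ,
                 drop = FALSE]
    frontier <- seed_pos
    fa <- srow$allele1; fb <- srow$allele2
    i <- 1L
    while (i <= nrow(cand)) {
      q <- cand$pos[i]
      st <- link_step(labels, frontier, fa, fb, q, min_pair_reads,
                      max_noise_frac)
      if (is.null(st)) {
        i <- i + 1L
        next
      }
      chain <- rbind(chain, data.frame(pos = q, hapA = st$alleleA,
                                       hapB = st$alleleB,
                                       supportA = st$supportA,
                                       supportB = st$supportB))
      frontier <- q; fa <- st$alleleA; fb <- st$alleleB
      cand <- cand[cand$pos != q &
                     (if (dir == "right") cand$pos > q else cand$pos < q), ,
                   drop = FALSE]
      i <- 1L
    }
    if (nrow(cand)) broken[[dir]] <- TRUE
  }
  chain <- chain[order(chain$pos), ]
  rownames(chain) <- NULL
  structure(list(sites = chain, seed = seed_pos,
                 broken_left = broken[["left"]],
                 broken_right = broken[["right"]], region = region),
            class = "phased_haplotypes")
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat("<phased_haplotypes> ", x$region, ": ", nrow(x$sites),
      " haplotype-defining sites, span ", min(x$sites$pos), "-",
      max(x$sites$pos),
      if (x$broken_left || x$broken_right) "  [fragment]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Automatic seed-site selection near a region border
#'
#' Chooses the called het site nearest a region border that has at least
#' `min_pair_reads` border-extending passes per allele (a pass extends
#' across the border when its block crosses it natively, or reaches it and
#' the read continues past in read coordinates — a junction split) and
#' balanced allele support (minor/major >= `min_balance`; a genuine het
#' site at full depth is roughly balanced, whereas a sequencing-error pile
#' that sneaks past the 10-read floor is strongly skewed). This replaces
#' manual inspection of the alignments with a deterministic rule.
#'
#' @param labels a [label_reads()] result.
#' @param het_sites data.frame of called het sites.
#' @param aln alignment-block data.frame the labels were built from.
#' @param map a [region_map()].
#' @param region region being phased.
#' @param min_pair_reads support per allele required at the seed.
#' @param end_tolerance border tolerance in bp.
#' @param min_balance minimum minor/major allele-support ratio at the seed.
#' @param exclude positions to skip (e.g. seeds already tried).
#' @return seed position.
#' @export
select_seed_site <- function(labels, het_sites, aln, map, region,
                             min_pair_reads = 5, end_tolerance = 100,
                             min_balance = 0.25, exclude = numeric(0)) {
  het_sites <- het_sites[!het_sites$pos %in% exclude, , drop = FALSE]
  if (!nrow(het_sites)) stop("no het sites to seed from")
  r <- region_row(map, region)
  d_start <- het_sites$pos - r$start
  d_end <- r$end - het_sites$pos
  balance <- pmin(het_sites$n1, het_sites$n2) /
    pmax(het_sites$n1, het_sites$n2)
  ord <- order(pmin(d_start, d_end))
  ord <- c(ord[balance[ord] >= min_balance], ord[balance[ord] < min_balance])
  best_fallback <- NULL; best_count <- -1
  for (i in ord) {
    pos <- het_sites$pos[i]
    side <- if (d_start[i] <= d_end[i]) "left" else "right"
    j <- match(pos, labels$pos)
    col <- labels$mat[, j]
    ext <- pass_extends(aln, labels$block, map, region, side, end_tolerance)
    n1 <- sum(col == het_sites$allele1[i] & ext, na.rm = TRUE)
    n2 <- sum(col == het_sites$allele2[i] & ext, na.rm = TRUE)
    if (n1 >= min_pair_reads && n2 >= min_pair_reads)
      return(pos)
    if (min(n1, n2) > best_count) {
      best_count <- min(n1, n2); best_fallback <- pos
    }
  }
  best_fallback
}

## does each pass (alignment block) extend across the region border?
pass_extends <- function(aln, blocks, map, region, side, end_tolerance) {
  r <- region_row(map, region)
  b <- aln[blocks, ]
  if (side == "left") {
    crossed <- b$ref_start < r$start
    reaches <- b$ref_start <= r$start + end_tolerance
    continues <- ifelse(b$strand == "+", b$read_start > 1,
                        b$read_end < b$read_len)
  } else {
    crossed <- b$ref_end > r$end
    reaches <- b$ref_end >= r$end - end_tolerance
    continues <- ifelse(b$strand == "+", b$read_end < b$read_len,
                        b$read_start > 1)
  }
  crossed | (reaches & continues)
}

## continuation context of one pass beyond a region border, in the
## canonical region-forward (reference) frame. Returns c(region, orient)
## or NULL.
pass_context <- function(aln, block_idx, map, region, side,
                         end_tolerance = 100) {
  r <- region_row(map, region)
  b <- aln[block_idx, ]
  border_in <- if (side == "left") r$start else r$end
  beyond <- if (side == "left") r$start - 1 else r$end + 1
  if ((side == "left" && b$ref_start < r$start) ||
      (side == "right" && b$ref_end > r$end)) {
    ## native crossing within the same block
    reg <- point_region(map, beyond)
    if (is.na(reg)) return(NULL)
    return(c(reg, "+"))
  }
  reaches <- if (side == "left") b$ref_start <= r$start + end_tolerance
             else b$ref_end >= r$end - end_tolerance
  if (!reaches) return(NULL)
  ## junction continuation: adjacent block on the matching read side
  sibs <- which(aln$read_id == b$read_id)
  sibs <- sibs[order(aln$read_start[sibs])]
  k <- match(block_idx, sibs)
  want_prev <- (side == "left") == (b$strand == "+")
  adj <- if (want_prev) {
    if (k == 1L) return(NULL) else sibs[k - 1L]
  } else {
    if (k == length(sibs)) return(NULL) else sibs[k + 1L]
  }
  a <- aln[adj, ]
  orient <- if (a$strand == b$strand) "+" else "-"
  ## the neighbour's junction-adjacent endpoint identifies its region
  endpoint <- if (want_prev) {
    if (a$strand == "+") a$ref_end else a$ref_start
  } else {
    if (a$strand == "+") a$ref_start else a$ref_end
  }
  reg <- point_region(map, endpoint)
  if (is.na(reg)) return(NULL)
  c(reg, orient)
}

point_region <- function(map, pos) {
  i <- which(map$regions$start <= pos & pos <= map$regions$end)
  if (!length(i)) NA_character_ else map$regions$region[i[1]]
}

#' Anchor phased haplotypes to their junction contexts
#'
#' For each haplotype, the passes carrying its terminal alleles are
#' followed across the region borders: native block crossings and junction
#' splits both yield a (neighbour region, orientation) context in the
#' canonical region-forward frame. Passes reaching both borders give full
#' (left | right) contexts directly; every full context supported by at
#' least `min_support` passes is emitted (a haplotype mixing two physical
#' lineages — e.g. the shared-allele class of a heterozygote — correctly
#' yields both of its contexts). When no full context reaches the support
#' threshold, the majority single-side anchors are combined; absent or
#' tied evidence leaves the side unanchored (NA).
#'
#' @param phased a [extend_haplotypes()] result.
#' @param labels the [label_reads()] result used for phasing.
#' @param aln the alignment-block data.frame.
#' @param map a [region_map()].
#' @param min_support minimum passes per emitted context.
#' @param end_tolerance border tolerance in bp.
#' @return data.frame of observed contexts: `region`, `haplotype`,
#'   `left_region`, `left_orient`, `right_region`, `right_orient`,
#'   `support` — directly consumable by [scenario_consistency()] and
#'   [infer_genotype()].
#' @export
anchor_haplotypes <- function(phased, labels, aln, map, min_support = 5,
                              end_tolerance = 100) {
  region <- phased$region
  ch <- phased$sites
  tL <- ch$pos[1]; tR <- ch$pos[nrow(ch)]
  jL <- match(tL, labels$pos); jR <- match(tR, labels$pos)
  out <- list()
  for (hap in c("A", "B")) {
    aL <- if (hap == "A") ch$hapA[1] else ch$hapB[1]
    aR <- if (hap == "A") ch$hapA[nrow(ch)] else ch$hapB[nrow(ch)]
    uL <- which(!is.na(labels$mat[, jL]) & labels$mat[, jL] == aL)
    uR <- which(!is.na(labels$mat[, jR]) & labels$mat[, jR] == aR)
    ctxL <- lapply(uL, function(u)
      pass_context(aln, labels$block[u], map, region, "left", end_tolerance))
    ctxR <- lapply(uR, function(u)
      pass_context(aln, labels$block[u], map, region, "right", end_tolerance))
    keyL <- vapply(ctxL, function(x)
      if (is.null(x)) NA_character_ else paste0(x[1], x[2]), character(1))
    keyR <- vapply(ctxR, function(x)
      if (is.null(x)) NA_character_ else paste0(x[1], x[2]), character(1))
    ## full contexts from passes with evidence on both sides
    both <- intersect(uL[!is.na(keyL)], uR[!is.na(keyR)])
    rows <- NULL
    if (length(both)) {
      kk <- paste(keyL[match(both, uL)], keyR[match(both, uR)], sep = "|")
      tb <- sort(table(kk), decreasing = TRUE)
      tb <- tb[tb >= min_support]
      if (length(tb)) {
        rows <- do.call(rbind, lapply(names(tb), function(k) {
          parts <- strsplit(k, "|", fixed = TRUE)[[1]]
          data.frame(region = region, haplotype = hap,
                     left_region = sub("[+-]$", "", parts[1]),
                     left_orient = sub("^.*([+-])$", "\\1", parts[1]),
                     right_region = sub("[+-]$", "", parts[2]),
                     right_orient = sub("^.*([+-])$", "\\1", parts[2]),
                     support = as.integer(tb[[k]]))
        }))
      }
    }
    if (is.null(rows)) {
      maj <- function(keys) {
        keys <- keys[!is.na(keys)]
        if (!length(keys)) return(c(NA_character_, NA_character_, 0))
        tb <- sort(table(keys), decreasing = TRUE)
        if (tb[1] < min_support ||
            (length(tb) > 1 && tb[2] == tb[1]))
          return(c(NA_character_, NA_character_, 0))
        k <- names(tb)[1]
        c(sub("[+-]$", "", k), sub("^.*([+-])$", "\\1", k), tb[[1]])
      }
      ml <- maj(keyL); mr <- maj(keyR)
      rows <- data.frame(region = region, haplotype = hap,
                         left_region = ml[1], left_orient = ml[2],
                         right_region = mr[1], right_orient = mr[2],
                         support = min(as.integer(ml[3]),
                                       as.integer(mr[3])))
    }
    out[[hap]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
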