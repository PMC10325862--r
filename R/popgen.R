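#' Phased haplotype panel
#'
#' Container for the sweep scan: biallelic, phased alleles coded 0/1 over
#' strictly increasing positions, with a population label per haplotype
#' (ploidy 2: haplotypes `2k-1` and `2k` belong to sample `k`).
#'
#' @param geno integer matrix, haplotypes x sites, values 0/1.
#' @param pos numeric vector of 1-based site positions.
#' @param chrom chromosome name.
#' @param hap_pop character vector of population labels, one per
#'   haplotype (row).
#' @param samples optional data.frame `sample`, `pop` (derived from
#'   `hap_pop` when omitted).
#' @return object of class `hap_panel`.
#' @export
hap_panel <- function(geno, pos, chrom = "1", hap_pop,
                      samples = NULL) {
  geno <- as.matrix(geno)
  stopifnot(all(geno %in% c(0L, 1L)), length(pos) == ncol(geno),
            length(hap_pop) == nrow(geno))
  if (is.unsorted(pos, strictly = TRUE))
    stop("site positions must be strictly increasing")
  if (nrow(geno) %% 2L != 0L)
    stop("ploidy 2: haplotype count must be even")
  if (is.null(samples)) {
    k <- nrow(geno) / 2
    samples <- data.frame(sample = paste0(hap_pop[2 * seq_len(k)], "_",
                                          seq_len(k)),
                          pop = hap_pop[2 * seq_len(k)])
  }
  structure(list(geno = geno, pos = as.numeric(pos), chrom = chrom,
                 hap_pop = as.character(hap_pop), samples = samples),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", nrow(x$geno), " haplotypes x ",
      ncol(x$geno), " sites on ", x$chrom, "; populations: ",
      paste(sprintf("%s(%d)", names(table(x$hap_pop)), table(x$hap_pop)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

pop_rows <- function(panel, pop) {
  if (is.null(pop)) seq_len(nrow(panel$geno))
  else which(panel$hap_pop == pop)
}

#' Tile non-overlapping windows across a span
#'
#' Windows are tiled from position 1 (or `from`); the last window may be
#' short and is flagged `partial`.
#'
#' @param to last position covered.
#' @param size window size in bp (default 50 Kb).
#' @param from first position (default 1).
#' @return data.frame `start`, `end`, `partial`.
#' @export
make_windows <- function(to, size = 50000, from = 1) {
  starts <- seq(from, to, by = size)
  ends <- pmin(starts + size - 1, to)
  data.frame(start = starts, end = ends, partial = ends - starts + 1 < size)
}

## --- neutrality statistics -------------------------------------------------

harmonic <- function(n, p = 1) sum(1 / (seq_len(n - 1))^p)

#' Tajima's D
#'
#' Variance-normalized difference between the mean-pairwise-difference and
#' Watterson estimates of theta (Tajima 1989 constants).
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes.
#' @param pi_total sum over sites of mean pairwise differences
#'   (unnormalized by length).
#' @return D, or NA when `S` = 0.
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* (outgroup-free)
#'
#' The starred, singleton-based form of Fu and Li's test, appropriate for
#' folded spectra: contrasts the total number of segregating sites with
#' the number of singletons (alleles seen in exactly one haplotype).
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes.
#' @param eta_s number of singletons.
#' @return D*, or NA when `S` = 0.
#' @export
fu_li_d_star <- function(S, n, eta_s) {
  if (S == 0 || n < 4) return(NA_real_)
  a <- harmonic(n); b <- harmonic(n, 2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- n / (n - 1) * (a - n / (n - 1)) - vD
  (n / (n - 1) * S - a * eta_s) / sqrt(uD * S + vD * S^2)
}

#' Windowed within-population diversity statistics
#'
#' Per window: segregating sites S, nucleotide diversity pi (mean pairwise
#' differences per effective site), Watterson's theta_W = S / (a_n x
#' effective sites), Tajima's D and Fu & Li's D* (folded, singleton-based).
#' Effective sites default to the window width and can be restricted by a
#' callability mask.
#'
#' @param panel a [hap_panel()].
#' @param windows data.frame from [make_windows()] (default tiles the
#'   panel's position range with 50 Kb windows).
#' @param pop population label (default: all haplotypes).
#' @param callable optional mask data.frame (`start`, `end`, 1-based
#'   inclusive) of callable intervals.
#' @return the windows data.frame with `n`, `S`, `eta_s`, `pi`, `theta_w`,
#'   `tajimas_d`, `fu_li_d_star`, `eff_sites` columns.
#' @export
diversity_stats <- function(panel, windows = NULL, pop = NULL,
                            callable = NULL) {
  rows <- pop_rows(panel, pop)
  n <- length(rows)
  if (n < 2) stop("need >= 2 haplotypes")  # D and D* are NA below n = 4
  if (is.null(windows)) windows <- make_windows(max(panel$pos))
  cnt <- colSums(panel$geno[rows, , drop = FALSE])
  seg <- cnt > 0 & cnt < n
  pi_site <- 2 * cnt * (n - cnt) / (n * (n - 1))
  single <- cnt == 1 | cnt == n - 1
  wi <- findInterval(panel$pos, windows$start)
  in_any <- wi >= 1 & panel$pos <= windows$end[pmax(wi, 1)]
  agg <- function(x) {
    out <- numeric(nrow(windows))
    s <- rowsum(x[in_any], wi[in_any])
    out[as.integer(rownames(s))] <- s
    out
  }
  S <- agg(as.numeric(seg))
  eta_s <- agg(as.numeric(seg & single))
  pi_tot <- agg(pi_site)
  eff <- effective_sites(windows, callable)
  windows$n <- n
  windows$S <- as.integer(S)
  windows$eta_s <- as.integer(eta_s)
  windows$pi <- ifelse(eff > 0, pi_tot / eff, NA_real_)
  windows$theta_w <- ifelse(eff > 0, S / (harmonic(n) * eff), NA_real_)
  windows$tajimas_d <- vapply(seq_len(nrow(windows)), function(i)
    tajimas_d(S[i], n, pi_tot[i]), numeric(1))
  windows$fu_li_d_star <- vapply(seq_len(nrow(windows)), function(i)
    fu_li_d_star(S[i], n, eta_s[i]), numeric(1))
  windows$eff_sites <- eff
  windows
}

effective_sites <- function(windows, callable) {
  if (is.null(callable)) return(windows$end - windows$start + 1)
  w <- IRanges::IRanges(windows$start, windows$end)
  m <- IRanges::reduce(IRanges::IRanges(callable$start, callable$end))
  ov <- IRanges::findOverlaps(w, m)
  width_ov <- IRanges::width(IRanges::pintersect(
    w[S4Vectors::queryHits(ov)], m[S4Vectors::subjectHits(ov)]))
  out <- numeric(nrow(windows))
  s <- rowsum(width_ov, S4Vectors::queryHits(ov))
  out[as.integer(rownames(s))] <- s
  out
}

## per-site Hudson components for a population pair
hudson_site_components <- function(panel, pop1, pop2) {
  r1 <- pop_rows(panel, pop1); r2 <- pop_rows(panel, pop2)
  n1 <- length(r1); n2 <- length(r2)
  c1 <- colSums(panel$geno[r1, , drop = FALSE])
  c2 <- colSums(panel$geno[r2, , drop = FALSE])
  p1 <- c1 / n1; p2 <- c2 / n2
  hw <- (2 * c1 * (n1 - c1) / (n1 * (n1 - 1)) +
           2 * c2 * (n2 - c2) / (n2 * (n2 - 1))) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  poly <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
  list(hw = hw, hb = hb, poly = poly, p1 = p1, p2 = p2)
}

#' Windowed Hudson F_ST and D_xy for a population pair
#'
#' Hudson's F_ST as a ratio of averages per window (1 - mean within-pair
#' heterozygosity / mean between-pair heterozygosity over sites
#' polymorphic in the pair; negative estimates are preserved) and absolute
#' divergence D_xy (mean between-population pairwise difference over
#' effective sites; all sites contribute).
#'
#' @param panel a [hap_panel()].
#' @param pop1,pop2 population labels.
#' @inheritParams diversity_stats
#' @return windows data.frame with `fst`, `dxy`, `n_poly`, `eff_sites`.
#' @export
differentiation_stats <- function(panel, pop1, pop2, windows = NULL,
                                  callable = NULL) {
  if (is.null(windows)) windows <- make_windows(max(panel$pos))
  h <- hudson_site_components(panel, pop1, pop2)
  wi <- findInterval(panel$pos, windows$start)
  in_any <- wi >= 1 & panel$pos <= windows$end[pmax(wi, 1)]
  agg <- function(x, sel = in_any) {
    out <- numeric(nrow(windows))
    s <- rowsum(x[sel], wi[sel])
    out[as.integer(rownames(s))] <- s
    out
  }
  hw_sum <- agg(ifelse(h$poly, h$hw, 0))
  hb_sum <- agg(ifelse(h$poly, h$hb, 0))
  n_poly <- agg(as.numeric(h$poly))
  hb_all <- agg(h$hb)
  eff <- effective_sites(windows, callable)
  windows$fst <- ifelse(hb_sum > 0, 1 - hw_sum / hb_sum, NA_real_)
  windows$dxy <- ifelse(eff > 0, hb_all / eff, NA_real_)
  windows$n_poly <- as.integer(n_poly)
  windows$eff_sites <- eff
  windows
}

#' Per-site Hudson F_ST
#'
#' @inheritParams differentiation_stats
#' @return data.frame `pos`, `p1`, `p2`, `fst` over sites polymorphic in
#'   the pair.
#' @export
per_site_fst <- function(panel, pop1, pop2) {
  h <- hudson_site_components(panel, pop1, pop2)
  sel <- h$poly & h$hb > 0
  data.frame(pos = panel$pos[sel], p1 = h$p1[sel], p2 = h$p2[sel],
             fst = 1 - h$hw[sel] / h$hb[sel])
}

#' Sites fixed (or nearly fixed) between two populations
#'
#' @inheritParams differentiation_stats
#' @param fst_threshold per-site Hudson F_ST cutoff (default 0.9).
#' @return subset of [per_site_fst()] rows with `fst > fst_threshold`.
#' @export
fixed_sites <- function(panel, pop1, pop2, fst_threshold = 0.9) {
  ps <- per_site_fst(panel, pop1, pop2)
  ps[ps$fst > fst_threshold, , drop = FALSE]
}

#' Count private alleles of a focal population
#'
#' Counts alleles present in the focal population and absent from every
#' comparison population; an optional exclusion list of positions (e.g.
#' known database alleles) is honored.
#'
#' @param panel a [hap_panel()].
#' @param focal focal population label.
#' @param comparison character vector of comparison population labels.
#' @param exclude_pos positions to skip.
#' @return integer count of private alleles.
#' @export
private_alleles <- function(panel, focal, comparison,
                            exclude_pos = NULL) {
  keep <- if (is.null(exclude_pos)) rep(TRUE, length(panel$pos))
          else !(panel$pos %in% exclude_pos)
  rf <- pop_rows(panel, focal)
  cf <- colSums(panel$geno[rf, , drop = FALSE])
  nf <- length(rf)
  comp <- lapply(comparison, function(p) {
    r <- pop_rows(panel, p)
    list(c = colSums(panel$geno[r, , drop = FALSE]), n = length(r))
  })
  alt_absent <- Reduce(`&`, lapply(comp, function(x) x$c == 0))
  ref_absent <- Reduce(`&`, lapply(comp, function(x) x$c == x$n))
  sum(keep & cf > 0 & alt_absent) + sum(keep & cf < nf & ref_absent)
}

#' Flag windows by callability and repeat content
#'
#' A window fails when its callable fraction is below `min_callable` or
#' its repeat fraction above `max_repeat`; failures are excluded from
#' outlier ranking but still reported.
#'
#' @param windows data.frame from [make_windows()].
#' @param callable,repeats mask data.frames (`start`, `end`, 1-based
#'   inclusive) or BED file paths (0-based half-open; read via
#'   rtracklayer). NULL masks pass every window with a warning.
#' @param min_callable minimum callable fraction (default 0.8).
#' @param max_repeat maximum repeat fraction (default 0.1).
#' @return windows with `callable_frac`, `repeat_frac`, `pass`.
#' @export
window_filters <- function(windows, callable = NULL, repeats = NULL,
                           min_callable = 0.8, max_repeat = 0.1) {
  if (is.character(callable)) callable <- read_mask_bed(callable)
  if (is.character(repeats)) repeats <- read_mask_bed(repeats)
  width <- windows$end - windows$start + 1
  if (is.null(callable)) {
    warning("no callability mask: all windows treated as fully callable")
    windows$callable_frac <- 1
  } else {
    windows$callable_frac <- effective_sites(windows, callable) / width
  }
  if (is.null(repeats)) {
    windows$repeat_frac <- 0
  } else {
    windows$repeat_frac <- effective_sites(windows, repeats) / width
  }
  windows$pass <- windows$callable_frac >= min_callable &
    windows$repeat_frac <= max_repeat
  windows
}

#' Empirical-quantile outlier windows, merged
#'
#' Outliers are passing windows at or above the `1 - top_frac` quantile of
#' the metric; adjoining outlier windows are merged (bookended-merge
#' semantics). F_ST scans conventionally use `top_frac = 0.01`, D_xy
#' scans 0.10.
#'
#' @param stats windows data.frame carrying the metric and (optionally) a
#'   `pass` column from [window_filters()].
#' @param metric column name to rank.
#' @param top_frac upper tail fraction.
#' @return data.frame of merged outlier intervals: `start`, `end`,
#'   `n_windows`, `max_metric`; attribute `threshold`.
#' @export
outlier_windows <- function(stats, metric = "fst", top_frac = 0.01) {
  pass <- if ("pass" %in% names(stats)) stats$pass else rep(TRUE, nrow(stats))
  x <- stats[[metric]]
  usable <- pass & !is.na(x)
  if (sum(usable) < 1 / top_frac) {
    warning("fewer than 1/top_frac usable windows; returning the best one")
    i <- which(usable)[which.max(x[usable])]
    out <- data.frame(start = stats$start[i], end = stats$end[i],
                      n_windows = 1L, max_metric = x[i])
    attr(out, "threshold") <- x[i]
    return(out)
  }
  thr <- stats::quantile(x[usable], 1 - top_frac, names = FALSE)
  idx <- which(usable & x >= thr)
  if (!length(idx)) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      n_windows = integer(0), max_metric = numeric(0))
    attr(out, "threshold") <- thr
    return(out)
  }
  ## bookended merge over genomic coordinates
  grp <- cumsum(c(TRUE, stats$start[idx[-1]] > stats$end[idx[-length(idx)]] + 1))
  out <- do.call(rbind, lapply(split(idx, grp), function(ii)
    data.frame(start = min(stats$start[ii]), end = max(stats$end[ii]),
               n_windows = length(ii), max_metric = max(x[ii]))))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
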