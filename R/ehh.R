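## Extended haplotype homozygosity and derived sweep statistics.
##
## EHH at distance d from a core site is the probability that two random
## carrier haplotypes of a core allele are identical over the interval
## from the core out to d; iHH is its trapezoid integral over physical
## distance, truncated where EHH decays below a floor. iHS contrasts the
## two core alleles (unpolarized: the majority allele plays the ancestral
## role); XP-EHH contrasts the pooled-core integrals of two populations.

group_homozygosity <- function(g) {
  n <- length(g)
  if (n < 2) return(NA_real_)
  tb <- tabulate(g)
  sum(tb * (tb - 1)) / (n * (n - 1))
}

## walk outward from core refining a grouping vector; returns the EHH
## curve (distance from core, ehh) on one side
ehh_side <- function(geno, pos, core_idx, carriers, dir, min_ehh,
                     max_gap, start_group = NULL) {
  n <- length(carriers)
  g <- if (is.null(start_group)) rep(1L, n) else start_group
  h0 <- group_homozygosity(g)
  steps <- if (dir > 0) seq_len(ncol(geno) - core_idx) + core_idx
           else rev(seq_len(core_idx - 1L))
  dist <- 0
  ehh <- h0
  last_pos <- pos[core_idx]
  for (j in steps) {
    if (abs(pos[j] - last_pos) > max_gap) break
    gn <- 2L * g + geno[carriers, j]  # alleles are 0/1: exact refinement
    g <- match(gn, unique(gn))
    h <- group_homozygosity(g)
    dist <- c(dist, abs(pos[j] - pos[core_idx]))
    ehh <- c(ehh, h)
    last_pos <- pos[j]
    if (h / h0 < min_ehh || h == 0) break
  }
  data.frame(dist = dist, ehh = ehh / h0)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' EHH decay and integrated haplotype homozygosity at a core site
#'
#' Computes, per core allele, the EHH decay curve in both directions and
#' its physical-distance integral iHH (trapezoid rule, integrated until
#' EHH falls below `min_ehh`; inter-site gaps larger than `max_gap` stop
#' the integration). The unstandardized iHS is
#' `ln(iHH_majority / iHH_minority)`.
#'
#' @param panel a [hap_panel()].
#' @param core core site position (must be a panel site).
#' @param pop population label (default all haplotypes).
#' @param min_ehh EHH floor (default 0.05).
#' @param max_gap maximum inter-site gap in bp (default 200 Kb).
#' @return list: `curves` (per-allele data.frames `dist`, `ehh`), `ihh`
#'   (named numeric, alleles "0"/"1"), `freq` (allele-1 frequency),
#'   `ihs_unstd` (ln iHH_major/iHH_minor, NA when an allele has < 2
#'   carriers).
#' @export
ehh_decay <- function(panel, core, pop = NULL, min_ehh = 0.05,
                      max_gap = 200000) {
  ci <- match(core, panel$pos)
  if (is.na(ci)) stop("core site not in panel")
  rows <- pop_rows(panel, pop)
  alleles <- panel$geno[rows, ci]
  curves <- list(); ihh <- c("0" = NA_real_, "1" = NA_real_)
  for (al in c(0L, 1L)) {
    carriers <- rows[alleles == al]
    if (length(carriers) < 2) next
    left <- ehh_side(panel$geno, panel$pos, ci, carriers, -1L, min_ehh,
                     max_gap)
    right <- ehh_side(panel$geno, panel$pos, ci, carriers, 1L, min_ehh,
                      max_gap)
    ihh[as.character(al)] <- trapezoid(left$dist, left$ehh) +
      trapezoid(right$dist, right$ehh)
    curves[[as.character(al)]] <- list(left = left, right = right)
  }
  p1 <- mean(alleles)
  maj <- if (p1 >= 0.5) "1" else "0"
  minr <- if (p1 >= 0.5) "0" else "1"
  ihs_unstd <- if (all(is.finite(ihh)) && ihh[minr] > 0)
    log(ihh[[maj]] / ihh[[minr]]) else NA_real_
  list(curves = curves, ihh = ihh, freq = p1, ihs_unstd = ihs_unstd)
}

#' Genome-wide iHS scan
#'
#' Unstandardized scores per site are standardized to mean 0, SD 1 within
#' minority-allele-frequency bins (default 20 equal-frequency bins), the
#' unpolarized analogue of derived-allele-frequency binning.
#'
#' @param panel a [hap_panel()].
#' @param pop population label.
#' @param min_maf minimum minor allele frequency for scoring.
#' @param n_bins number of frequency bins for standardization.
#' @inheritParams ehh_decay
#' @return data.frame `pos`, `maf`, `ihs_unstd`, `ihs`.
#' @export
ihs_scan <- function(panel, pop = NULL, min_maf = 0.05, n_bins = 20,
                     min_ehh = 0.05, max_gap = 200000) {
  rows <- pop_rows(panel, pop)
  p1 <- colMeans(panel$geno[rows, , drop = FALSE])
  maf <- pmin(p1, 1 - p1)
  idx <- which(maf >= min_maf)
  raw <- vapply(idx, function(i)
    ehh_decay(panel, panel$pos[i], pop, min_ehh, max_gap)$ihs_unstd,
    numeric(1))
  out <- data.frame(pos = panel$pos[idx], maf = maf[idx], ihs_unstd = raw)
  ok <- is.finite(out$ihs_unstd)
  out$ihs <- NA_real_
  if (sum(ok) >= 2) {
    nb <- max(1L, min(n_bins, floor(sum(ok) / 10)))
    br <- unique(stats::quantile(out$maf[ok], probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(out$maf, breaks = br, include.lowest = TRUE)
    for (b in levels(bin)) {
      sel <- ok & !is.na(bin) & bin == b
      if (sum(sel) >= 2) {
        mu <- mean(out$ihs_unstd[sel]); sdv <- stats::sd(out$ihs_unstd[sel])
        if (sdv > 0) out$ihs[sel] <- (out$ihs_unstd[sel] - mu) / sdv
      }
    }
  }
  out
}

## pooled-core integrated EHH for one population (EHHS normalized to 1 at
## the core, grouping initialized by the core alleles)
ies_site <- function(panel, ci, pop, min_ehh, max_gap) {
  rows <- pop_rows(panel, pop)
  g0 <- panel$geno[rows, ci] + 1L
  if (length(rows) < 2) return(NA_real_)
  left <- ehh_side(panel$geno, panel$pos, ci, rows, -1L, min_ehh, max_gap,
                   start_group = g0)
  right <- ehh_side(panel$geno, panel$pos, ci, rows, 1L, min_ehh, max_gap,
                    start_group = g0)
  trapezoid(left$dist, left$ehh) + trapezoid(right$dist, right$ehh)
}

#' Cross-population EHH scan (XP-EHH)
#'
#' Per site, `ln(iES_pop1 / iES_pop2)` of the pooled-core integrated EHH,
#' standardized genome-wide to mean 0, SD 1. Positive scores indicate
#' longer haplotype homozygosity in `pop1`.
#'
#' @param panel a [hap_panel()].
#' @param pop1,pop2 population labels (scores are pop1 relative to pop2).
#' @inheritParams ihs_scan
#' @return data.frame `pos`, `xpehh_unstd`, `xpehh`.
#' @export
xpehh_scan <- function(panel, pop1, pop2, min_maf = 0.05,
                       min_ehh = 0.05, max_gap = 200000) {
  p_all <- colMeans(panel$geno)
  maf <- pmin(p_all, 1 - p_all)
  idx <- which(maf >= min_maf)
  raw <- vapply(idx, function(i) {
    a <- ies_site(panel, i, pop1, min_ehh, max_gap)
    b <- ies_site(panel, i, pop2, min_ehh, max_gap)
    if (is.finite(a) && is.finite(b) && a > 0 && b > 0) log(a / b)
    else NA_real_
  }, numeric(1))
  out <- data.frame(pos = panel$pos[idx], xpehh_unstd = raw)
  ok <- is.finite(raw)
  out$xpehh <- NA_real_
  if (sum(ok) >= 2) {
    mu <- mean(raw[ok]); sdv <- stats::sd(raw[ok])
    if (sdv > 0) out$xpehh[ok] <- (raw[ok] - mu) / sdv
  }
  out
}
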