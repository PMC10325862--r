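#' Simulate a multi-population phased haplotype panel
#'
#' Neutral sites receive allele counts drawn from the neutral site
#' frequency spectrum (count `i` with probability proportional to `1/i`,
#' equivalently folded probability proportional to `1/i + 1/(n-i)`);
#' population differentiation is induced Balding-Nichols style, drawing
#' each population's allele frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p` with
#' an independent drift parameter `F` per population. An optional sweep
#' plants a single swept haplotype at a configured frequency in a target
#' population across a window, creating long-range homozygosity and
#' reduced local diversity.
#'
#' @param n_pops number of populations (>= 2 for differentiation).
#' @param haps_per_pop haplotypes per population (>= 4; even).
#' @param n_sites number of polymorphic sites.
#' @param span chromosome length in bp.
#' @param drift per-population drift parameter F (recycled; 0 = no drift,
#'   counts drawn directly from the pooled neutral SFS).
#' @param sweep NULL or list(`pop`, `center`, `width`, `freq`): the swept
#'   haplotype's frequency must lie in (0, 1].
#' @param pop_names population labels.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list: `panel` ([hap_panel()]), `truth` (drift and sweep
#'   settings, swept haplotype ids).
#' @export
simulate_panel <- function(n_pops = 2, haps_per_pop = 18, n_sites = 5000,
                           span = 1e6, drift = 0, sweep = NULL,
                           pop_names = paste0("pop", seq_len(n_pops)),
                           seed = 1L, chrom = "panel") {
  stopifnot(n_pops >= 2, haps_per_pop >= 4)
  if (!is.null(sweep)) {
    stopifnot(all(c("pop", "center", "width", "freq") %in% names(sweep)))
    if (sweep$freq <= 0 || sweep$freq > 1)
      stop("sweep frequency must lie in (0, 1]")
  }
  set.seed(seed)
  drift <- rep_len(drift, n_pops)
  N <- n_pops * haps_per_pop
  pos <- sort(sample.int(span, n_sites))
  hap_pop <- rep(pop_names, each = haps_per_pop)
  geno <- matrix(0L, nrow = N, ncol = n_sites)
  sfs_w <- 1 / seq_len(N - 1)
  counts <- sample.int(N - 1, n_sites, replace = TRUE, prob = sfs_w)
  if (all(drift == 0)) {
    for (j in seq_len(n_sites))
      geno[sample.int(N, counts[j]), j] <- 1L
  } else {
    draw_drifted <- function(sites) {
      p_anc <- sample.int(N - 1, length(sites), replace = TRUE,
                          prob = sfs_w) / N
      for (k in seq_len(n_pops)) {
        rows <- which(hap_pop == pop_names[k])
        Fk <- drift[k]
        pk <- if (Fk > 0)
          stats::rbeta(length(sites), p_anc * (1 - Fk) / Fk,
                       (1 - p_anc) * (1 - Fk) / Fk)
        else p_anc
        ck <- stats::rbinom(length(sites), haps_per_pop, pk)
        for (jj in seq_along(sites)) {
          geno[rows, sites[jj]] <<- 0L
          if (ck[jj] > 0L)
            geno[rows[sample.int(haps_per_pop, ck[jj])], sites[jj]] <<- 1L
        }
      }
    }
    draw_drifted(seq_len(n_sites))
    ## redraw monomorphic sites under the same drift model so the panel
    ## stays polymorphic without diluting differentiation
    for (it in seq_len(200)) {
      tot <- colSums(geno)
      mono <- which(tot == 0L | tot == N)
      if (!length(mono)) break
      draw_drifted(mono)
    }
  }
  swept <- NULL
  if (!is.null(sweep)) {
    win <- which(pos >= sweep$center - sweep$width / 2 &
                   pos <= sweep$center + sweep$width / 2)
    rows <- which(hap_pop == sweep$pop)
    donor <- rows[1]
    m <- max(1L, round(sweep$freq * length(rows)))
    swept <- sort(c(donor, sample(setdiff(rows, donor), m - 1L)))
    if (length(win))
      geno[swept, win] <- matrix(geno[donor, win], nrow = length(swept),
                                 ncol = length(win), byrow = TRUE)
  }
  panel <- hap_panel(geno, pos, chrom = chrom, hap_pop = hap_pop)
  list(panel = panel,
       truth = list(drift = stats::setNames(drift, pop_names),
                    sweep = sweep, swept_haplotypes = swept, span = span))
}

#' Simulate callability and repeat masks
#'
#' Random low-callability and repeat patches over a span; the callable
#' mask is the complement of the low-callability patches.
#'
#' @param span chromosome length in bp.
#' @param n_low,low_width number and width of low-callability patches.
#' @param n_repeat,repeat_width number and width of repeat patches.
#' @param seed integer seed.
#' @return list of mask data.frames `callable` and `repeats`
#'   (`start`, `end`, 1-based inclusive).
#' @export
simulate_masks <- function(span, n_low = 2, low_width = 40000,
                           n_repeat = 2, repeat_width = 20000, seed = 1L) {
  set.seed(seed)
  patch <- function(n, w) {
    if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
    s <- sort(sample.int(span - w, n))
    data.frame(start = s, end = s + w - 1)
  }
  low <- patch(n_low, low_width)
  reps <- patch(n_repeat, repeat_width)
  callable <- if (nrow(low)) {
    keep <- IRanges::setdiff(IRanges::IRanges(1, span),
                             IRanges::IRanges(low$start, low$end))
    data.frame(start = IRanges::start(keep), end = IRanges::end(keep))
  } else data.frame(start = 1, end = span)
  list(callable = callable, repeats = reps)
}
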