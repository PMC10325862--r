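#' Windowed read coverage
#'
#' Counts reads per non-overlapping window tiled across a span (bedtools
#' makewindows/coverage semantics: the last window may be short; a read is
#' counted once in every window its alignment overlaps). Values are
#' normalized by the median window count so single-copy sequence sits near
#' 1 and duplicated sequence in a carrier near its relative copy number.
#'
#' @param aln alignment-block data.frame (long or short reads).
#' @param span numeric `c(start, end)` reference span to tile (default the
#'   range of the alignments).
#' @param window_size window width in bp (>= 100).
#' @return a `coverage_profile`: data.frame `start`, `end`, `count`,
#'   `norm`, with attributes `window_size` and `norm_const`.
#' @export
window_coverage <- function(aln, span = NULL, window_size = 1000) {
  stopifnot(window_size >= 100)
  if (is.null(span)) {
    if (nrow(aln) == 0L) stop("empty alignments and no span given")
    span <- c(min(aln$ref_start), max(aln$ref_end))
  }
  starts <- seq(span[1], span[2], by = window_size)
  ends <- pmin(starts + window_size - 1, span[2])
  counts <- integer(length(starts))
  if (nrow(aln) == 0L) {
    warning("empty alignment set: all-zero coverage profile")
  } else {
    win <- IRanges::IRanges(starts, ends)
    blk <- IRanges::IRanges(aln$ref_start, aln$ref_end)
    h <- IRanges::findOverlaps(win, blk)
    ## one count per (window, read) even if a read has several blocks there
    key <- paste0(S4Vectors::queryHits(h), "\r",
                  aln$read_id[S4Vectors::subjectHits(h)])
    wq <- S4Vectors::queryHits(h)[!duplicated(key)]
    tab <- tabulate(wq, nbins = length(starts))
    counts <- tab
  }
  med <- stats::median(counts)
  norm <- if (med > 0) counts / med else counts * NA_real_
  structure(data.frame(start = starts, end = ends, count = counts,
                       norm = norm),
            window_size = window_size, norm_const = med,
            class = c("coverage_profile", "data.frame"))
}

#' Detect duplication boundaries from windowed coverage
#'
#' Calls a boundary between adjacent windows where the case sample's
#' normalized coverage changes drastically while every control stays
#' quiet at the same position. The contrast is measured over the two
#' windows on either side of the candidate boundary (the means of windows
#' i-1..i vs i+1..i+2 must differ by `ratio_threshold`): a single-window
#' contrast is both noisier (paired reads double the window-count
#' variance) and blind to breakpoints falling mid-window, whose
#' intermediate window dilutes the adjacent-pair ratio. Runs of calls in
#' the same direction within two windows are collapsed to the strongest
#' one, so each breakpoint yields a single call, within one window of its
#' true position.
#'
#' @param case a [window_coverage()] profile for the candidate carrier.
#' @param controls list of profiles for non-carriers on the same windowing.
#' @param ratio_threshold adjacent-window ratio that counts as drastic
#'   (default 1.5 — halfway between single-copy 1x and duplicated 2x).
#' @return data.frame of breakpoint calls: `pos` (1-based first base of
#'   the right window), `side` (`rise`/`fall`), `left_norm`, `right_norm`,
#'   `ratio`, `refined` (FALSE), `confidence` (NA until refinement); the
#'   attribute `case_only` is TRUE when no controls were supplied.
#' @export
detect_boundaries <- function(case, controls = list(),
                              ratio_threshold = 1.5) {
  if (!length(controls)) {
    case_only <- TRUE
  } else {
    case_only <- FALSE
    for (ctl in controls)
      if (nrow(ctl) != nrow(case) ||
          any(ctl$start != case$start))
        stop("case and controls must share the same windowing")
  }
  nw <- nrow(case)
  ## short trailing windows have deflated counts by construction: they
  ## neither trigger a boundary nor enter the side means
  full <- (case$end - case$start + 1) == max(case$end - case$start + 1)
  pair_contrast <- function(v) {
    v <- ifelse(full, v, NA_real_)
    vapply(seq_len(nw - 1L), function(i) {
      lm <- mean(v[pmax(1, c(i - 1L, i))], na.rm = TRUE)
      rm <- mean(v[pmin(nw, c(i + 1L, i + 2L))], na.rm = TRUE)
      if (is.nan(lm) || is.nan(rm)) return(1)
      hi <- max(lm, rm); lo <- min(lm, rm)
      if (hi == 0) 1 else hi / max(lo, 1e-9)
    }, numeric(1))
  }
  rc <- pair_contrast(case$norm)
  hit <- rc >= ratio_threshold
  for (ctl in controls)
    hit <- hit & (pair_contrast(ctl$norm) < ratio_threshold)
  hit <- hit & full[-nw] & full[-1]
  idx <- which(hit)
  if (!length(idx)) {
    out <- data.frame(pos = numeric(0), side = character(0),
                      left_norm = numeric(0), right_norm = numeric(0),
                      ratio = numeric(0), refined = logical(0),
                      confidence = numeric(0))
    attr(out, "case_only") <- case_only
    return(out)
  }
  vfull <- ifelse(full, case$norm, NA_real_)
  lmean <- vapply(idx, function(i)
    mean(vfull[pmax(1, c(i - 1L, i))], na.rm = TRUE), numeric(1))
  rmean <- vapply(idx, function(i)
    mean(vfull[pmin(nw, c(i + 1L, i + 2L))], na.rm = TRUE), numeric(1))
  side <- ifelse(rmean > lmean, "rise", "fall")
  calls <- data.frame(pos = case$start[idx + 1], side = side,
                      left_norm = lmean, right_norm = rmean,
                      ratio = rc[idx], refined = FALSE,
                      confidence = NA_real_, win = idx)
  ## collapse same-direction runs within 2 windows, keep the strongest
  keep <- logical(nrow(calls))
  grp <- cumsum(c(TRUE, diff(calls$win) > 2 |
                    calls$side[-1] != calls$side[-nrow(calls)]))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    keep[rows[which.max(calls$ratio[rows])]] <- TRUE
  }
  out <- calls[keep, setdiff(names(calls), "win"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "case_only") <- case_only
  out
}

#' Per-base depth track from alignment blocks
#'
#' @param aln alignment-block data.frame.
#' @param span numeric `c(start, end)` reference span.
#' @return integer vector of depth, position `span[1]` first.
#' @export
depth_track <- function(aln, span) {
  cov <- IRanges::coverage(IRanges::IRanges(aln$ref_start, aln$ref_end),
                           width = span[2])
  as.integer(cov)[span[1]:span[2]]
}

#' Refine a window-resolution breakpoint to base pair resolution
#'
#' Fits a one-step (two-segment) mean model to per-base depth in a search
#' window around the call — the 1 bp-window analogue of narrowing a
#' coverage breakpoint. Because coverage noise is correlated over a read
#' length while junction-clipped reads pile their ends on the exact
#' breakpoint base, the least-squares changepoint is then snapped to the
#' strongest direction-consistent single-base depth jump in the window
#' whenever that jump carries at least half the fitted step (at one base,
#' the true breakpoint moves depth by the full step height; sampling
#' noise moves it by ~1 read). Confidence is the absolute mean shift over
#' the pooled within-segment SD; a flat profile
#' (confidence < `min_confidence`) leaves the windowed call unrefined.
#'
#' @param depth integer per-base depth vector.
#' @param offset reference coordinate of `depth[1]`.
#' @param call one row of [detect_boundaries()] output.
#' @param search_radius half-width of the refinement window in bp.
#' @param min_confidence minimum mean-shift/SD to accept a step.
#' @return the call row with `pos` refined (1-based first base of the
#'   right segment), `refined` and `confidence` filled in.
#' @export
refine_breakpoint <- function(depth, offset, call, search_radius = 2000,
                              min_confidence = 0.5) {
  lo <- max(1, call$pos - search_radius - offset + 1)
  hi <- min(length(depth), call$pos + search_radius - offset + 1)
  x <- as.numeric(depth[lo:hi])
  n <- length(x)
  if (n < 4) return(call)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ## candidate b = index of first base of the right segment (2..n)
  b <- 2:n
  nl <- b - 1; nr <- n - nl
  sl <- cs[nl]; sr <- cs[n] - sl
  ssl <- cs2[nl]; ssr <- cs2[n] - ssl
  sse <- (ssl - sl^2 / nl) + (ssr - sr^2 / nr)
  best <- which.min(sse)
  ml <- sl[best] / nl[best]; mr <- sr[best] / nr[best]
  pooled <- sqrt(sse[best] / max(n - 2, 1))
  shift <- abs(mr - ml)
  conf <- if (pooled > 0) shift / pooled else if (shift > 0) Inf else NaN
  if (is.nan(conf) || conf < min_confidence) {
    call$confidence <- conf
    return(call)  # flat profile: keep windowed call, refined stays FALSE
  }
  pos_ls <- offset + lo - 1 + (b[best] - 1)
  ## snap to the clip-pile jump when it is decisive
  dif <- diff(x)
  sgn <- if (identical(call$side, "fall")) -1 else 1
  j <- which.max(sgn * dif)
  if (sgn * dif[j] >= max(4, 0.5 * shift)) {
    call$pos <- offset + lo - 1 + j
  } else {
    call$pos <- pos_ls
  }
  call$refined <- TRUE
  call$confidence <- conf
  call
}

#' Classify a sample as Fm carrier or non-carrier
#'
#' Combines the two lines of evidence: normalized depth over both
#' duplicated regions elevated relative to the flanks, and read support for
#' both carrier-specific junctions (A and B). Junction reads are the
#' primary evidence: a heterozygote at ~1.5x relative depth is still
#' called a carrier through its junction reads, and a depth-only signal
#' without any junction read is called non-carrier and flagged discordant.
#'
#' @param profile a [window_coverage()] profile for the sample.
#' @param junction_counts result of [junction_support_table()] (or a named
#'   vector with elements `A` and `B`); NULL for depth-only classification.
#' @param map a [region_map()].
#' @param dup_ratio_threshold minimum Dup/flank normalized-depth ratio.
#' @param min_junction_reads minimum reads per junction type.
#' @return list: `carrier` (logical), `evidence` (list with the measured
#'   ratios and counts), `discordant`, `depth_only`.
#' @export
classify_carrier <- function(profile, junction_counts, map,
                             dup_ratio_threshold = 1.6,
                             min_junction_reads = 3) {
  win_mean <- function(region) {
    r <- region_row(map, region)
    sel <- profile$start <= r$end & profile$end >= r$start
    mean(profile$norm[sel])
  }
  flank <- mean(c(win_mean("Flank1"), win_mean("Flank2")))
  d1 <- win_mean("Dup1"); d2 <- win_mean("Dup2")
  depth_ok <- is.finite(flank) && flank > 0 &&
    d1 >= dup_ratio_threshold * flank && d2 >= dup_ratio_threshold * flank
  if (is.null(junction_counts)) {
    return(list(carrier = depth_ok,
                evidence = list(dup1_ratio = d1 / flank,
                                dup2_ratio = d2 / flank,
                                junction_A = NA, junction_B = NA),
                discordant = FALSE, depth_only = TRUE))
  }
  jA <- if (!is.null(junction_counts[["A"]])) junction_counts[["A"]] else 0
  jB <- if (!is.null(junction_counts[["B"]])) junction_counts[["B"]] else 0
  junction_ok <- jA >= min_junction_reads && jB >= min_junction_reads
  carrier <- if (depth_ok == junction_ok) junction_ok else junction_ok
  list(carrier = carrier,
       evidence = list(dup1_ratio = d1 / flank, dup2_ratio = d2 / flank,
                       junction_A = jA, junction_B = jB),
       discordant = depth_ok != junction_ok, depth_only = FALSE)
}
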