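#' Ranked sweep-candidate report
#'
#' Merges the F_ST outlier windows of a focal-vs-reference comparison and
#' annotates each candidate region with the corroborating statistics a
#' sweep should show: reduced focal diversity (pi ratio), negative focal
#' Tajima's D, elevated |iHS| in the focal population, positive XP-EHH
#' (focal over reference), membership in the D_xy top decile, and the
#' distance to the nearest duplicated region of the locus map when one is
#' supplied. Regions are ranked by their maximum F_ST.
#'
#' @param fst_windows windows data.frame from [differentiation_stats()]
#'   (with `pass` from [window_filters()] if masks are available).
#' @param div_focal,div_ref windows data.frames from [diversity_stats()]
#'   for the focal and reference populations (same windowing).
#' @param ihs data.frame from [ihs_scan()] on the focal population.
#' @param xpehh data.frame from [xpehh_scan()] (focal vs reference).
#' @param map optional [region_map()] for distance annotation.
#' @param top_frac_fst F_ST outlier tail (default 0.01).
#' @param top_frac_dxy D_xy high-divergence tail (default 0.10).
#' @return data.frame of candidate regions: `start`, `end`, `n_windows`,
#'   `fst_max`, `pi_ratio`, `tajimas_d_focal`, `mean_abs_ihs`,
#'   `mean_xpehh`, `dxy_top`, `dist_dup1`, ranked by `fst_max`.
#' @export
sweep_report <- function(fst_windows, div_focal, div_ref, ihs = NULL,
                         xpehh = NULL, map = NULL, top_frac_fst = 0.01,
                         top_frac_dxy = 0.10) {
  out <- outlier_windows(fst_windows, "fst", top_frac_fst)
  if (!nrow(out)) return(out)
  dxy_out <- outlier_windows(fst_windows, "dxy", top_frac_dxy)
  ann <- lapply(seq_len(nrow(out)), function(i) {
    s <- out$start[i]; e <- out$end[i]
    wsel <- div_focal$start <= e & div_focal$end >= s
    pi_f <- mean(div_focal$pi[wsel], na.rm = TRUE)
    pi_r <- mean(div_ref$pi[wsel], na.rm = TRUE)
    td <- mean(div_focal$tajimas_d[wsel], na.rm = TRUE)
    mi <- if (!is.null(ihs)) {
      sel <- ihs$pos >= s & ihs$pos <= e
      mean(abs(ihs$ihs[sel]), na.rm = TRUE)
    } else NA_real_
    mx <- if (!is.null(xpehh)) {
      sel <- xpehh$pos >= s & xpehh$pos <= e
      mean(xpehh$xpehh[sel], na.rm = TRUE)
    } else NA_real_
    dtop <- nrow(dxy_out) > 0 &&
      any(dxy_out$start <= e & dxy_out$end >= s)
    dd <- if (!is.null(map) && "Dup1" %in% map$regions$region) {
      r <- region_row(map, "Dup1")
      if (e < r$start) r$start - e
      else if (s > r$end) s - r$end
      else 0
    } else NA_real_
    data.frame(start = s, end = e, n_windows = out$n_windows[i],
               fst_max = out$max_metric[i],
               pi_ratio = pi_f / pi_r, tajimas_d_focal = td,
               mean_abs_ihs = mi, mean_xpehh = mx, dxy_top = dtop,
               dist_dup1 = dd)
  })
  res <- do.call(rbind, ann)
  res <- res[order(-res$fst_max), ]
  rownames(res) <- NULL
  res
}
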