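#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study conditions the simulator emulates at 1/10 scale: a diploid
#' carrier of the `*Fm_2` arrangement, ~1% heterozygous-site density between
#' the two copies of each duplicated region, log-normal long reads with a
#' 20 kb median and 5% substitution error at 60x diploid depth, and
#' 150 bp short reads at 30x.
#'
#' @param seed integer seed; a fixed seed reproduces byte-identical outputs.
#' @param map a [region_map()] (default the 1/10-scale locus).
#' @param arrangements character vector of two built-in arrangement names,
#'   or a list of two [arrangement()] objects — the two locus haplotypes of
#'   the diploid sample (e.g. `c("Fm_2", "Fm_2")` homozygote,
#'   `c("Fm_2", "N")` heterozygote).
#' @param het_density_dup per-bp density of planted sites distinguishing the
#'   two copies of each duplicated region.
#' @param het_density_bg per-bp density of ordinary chromosome-level
#'   heterozygous sites outside the duplicated regions.
#' @param long_read list: `meanlog`, `sdlog` (log-normal read length, bp),
#'   `min_len`, `error_rate` (i.i.d. per-base substitution), `depth`
#'   (diploid mean depth, x).
#' @param short_read list: `length`, `insert`, `insert_sd`, `depth`
#'   (diploid, x).
#' @param mega_reads logical; if TRUE the long-read length distribution is
#'   shifted so single reads typically span a whole duplicated region.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       map = region_map_from_lengths(),
                       arrangements = c("Fm_2", "Fm_2"),
                       het_density_dup = 0.01,
                       het_density_bg = 0.002,
                       long_read = list(),
                       short_read = list(),
                       mega_reads = FALSE) {
  lr <- utils::modifyList(list(meanlog = log(20000), sdlog = 0.55,
                               min_len = 300, error_rate = 0.05,
                               depth = 60), long_read)
  if (mega_reads) {
    dup_max <- max(vapply(c("Dup1", "Dup2"), function(r)
      region_length(map, r), numeric(1)))
    lr$meanlog <- log(2.5 * dup_max)
    lr$sdlog <- 0.25
  }
  sr <- utils::modifyList(list(length = 150, insert = 350, insert_sd = 35,
                               depth = 30), short_read)
  if (is.character(arrangements))
    arrangements <- lapply(arrangements, fm_arrangement)
  stopifnot(length(arrangements) == 2L,
            all(vapply(arrangements, inherits, logical(1), "arrangement")))
  if (het_density_dup < 0 || het_density_dup > 1 ||
      het_density_bg < 0 || het_density_bg > 1)
    stop("het densities must lie in [0, 1]")
  if (lr$error_rate < 0 || lr$error_rate > 1)
    stop("error_rate must lie in [0, 1]")
  if (lr$depth <= 0 || sr$depth <= 0)
    stop("depths must be positive")
  if (exp(lr$meanlog) < 50)
    stop("long-read length distribution has its mass below 50 bp")
  structure(list(seed = as.integer(seed), map = map,
                 arrangements = arrangements,
                 het_density_dup = het_density_dup,
                 het_density_bg = het_density_bg,
                 long_read = lr, short_read = sr),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  genotype:", x$arrangements[[1]]$name, "/",
      x$arrangements[[2]]$name, "\n")
  cat("  het density (dup/bg):", x$het_density_dup, "/",
      x$het_density_bg, "\n")
  cat("  long reads: median", round(exp(x$long_read$meanlog)), "bp,",
      x$long_read$depth, "x,", x$long_read$error_rate, "error\n")
  cat("  short reads:", x$short_read$length, "bp,",
      x$short_read$depth, "x\n")
  invisible(x)
}
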