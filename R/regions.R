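#' Region map of the Fm locus
#'
#' A region map names the five reference intervals that tile the locus:
#' `Flank1`, `Dup1`, `Int`, `Dup2`, `Flank2`. Coordinates are 1-based
#' inclusive reference coordinates; the intervals must be disjoint, sorted
#' and contiguous (each `end + 1` equals the next `start`).
#'
#' @param chrom chromosome name.
#' @param regions a data.frame with columns `region`, `start`, `end`,
#'   one row per named interval, in genomic order.
#' @return an object of class `region_map`.
#' @seealso [fm_region_map()] for the GRCg6a default,
#'   [region_map_from_lengths()] for scaled synthetic maps.
#' @export
region_map <- function(chrom, regions) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  stopifnot(is.data.frame(regions),
            all(c("region", "start", "end") %in% names(regions)))
  regions <- regions[, c("region", "start", "end")]
  regions$region <- as.character(regions$region)
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  if (anyDuplicated(regions$region))
    stop("region names must be unique")
  if (any(regions$end < regions$start))
    stop("each region must have end >= start (length >= 1)")
  n <- nrow(regions)
  if (n > 1L) {
    if (is.unsorted(regions$start, strictly = TRUE))
      stop("regions must be sorted by start")
    if (!all(regions$end[-n] + 1 == regions$start[-1]))
      stop("regions must be contiguous: end + 1 must equal the next start")
  }
  structure(list(chrom = chrom, regions = regions), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> ", x$chrom, ": ",
      x$regions$start[1], "-", x$regions$end[nrow(x$regions)], "\n", sep = "")
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    cat(sprintf("  %-8s %10.0f - %10.0f  (%s bp)\n", r$region, r$start, r$end,
                format(r$end - r$start + 1, big.mark = ",")))
  }
  invisible(x)
}

#' Default Fm locus region map (GRCg6a chromosome 20)
#'
#' Breakpoint coordinates of the duplicated regions on the un-rearranged
#' Gallus_gallus.GRCg6a reference: Dup1 20:10766772-10894151 and
#' Dup2 20:11306686-11477501, separated by the single-copy Int region and
#' bracketed by ~500 Kb flanks (Flank1 20:10263555-10766771,
#' Flank2 20:11477502-11980000).
#'
#' @return a [region_map()].
#' @export
fm_region_map <- function() {
  region_map("20", data.frame(
    region = c("Flank1", "Dup1", "Int", "Dup2", "Flank2"),
    start  = c(10263555, 10766772, 10894152, 11306686, 11477502),
    end    = c(10766771, 10894151, 11306685, 11477501, 11980000)
  ))
}

#' Build a region map from region lengths
#'
#' Convenience constructor for synthetic runs: the same five region names on
#' an arbitrary coordinate system starting at `start`. The default lengths
#' are a 1/10-scale locus (flanks rounded to 50 Kb) used throughout the
#' simulation defaults.
#'
#' @param lengths named numeric vector of region lengths in bp, in genomic
#'   order.
#' @param chrom chromosome name.
#' @param start 1-based coordinate of the first base of the first region.
#' @return a [region_map()].
#' @export
region_map_from_lengths <- function(lengths = c(Flank1 = 50000, Dup1 = 12738,
                                                Int = 41253, Dup2 = 17081,
                                                Flank2 = 50000),
                                    chrom = "locus", start = 1) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  ends <- start - 1 + cumsum(as.numeric(lengths))
  starts <- c(start, ends[-length(ends)] + 1)
  region_map(chrom, data.frame(region = names(lengths),
                               start = starts, end = ends))
}

region_row <- function(map, region) {
  i <- match(region, map$regions$region)
  if (is.na(i)) stop("unknown region name: ", region)
  map$regions[i, ]
}

#' Length of a named region
#'
#' @param map a [region_map()].
#' @param region region name present in the map.
#' @return length in bp (`end - start + 1`, 1-based inclusive convention).
#' @examples
#' region_length(fm_region_map(), "Dup1")  # 127380
#' @export
region_length <- function(map, region) {
  r <- region_row(map, region)
  r$end - r$start + 1
}

#' Region lengths in whole kilobases
#'
#' Floor-Kb convention used when quoting approximate region sizes
#' (e.g. Dup1 ~127 Kb, Int ~412 Kb, Dup2 ~170 Kb on GRCg6a).
#'
#' @inheritParams region_length
#' @return integer number of whole Kb.
#' @export
region_length_kb <- function(map, region) {
  floor(region_length(map, region) / 1000)
}

#' Total reference span of a region map
#' @param map a [region_map()].
#' @return numeric vector `c(start, end)` of the locus span.
#' @export
map_span <- function(map) {
  c(map$regions$start[1], map$regions$end[nrow(map$regions)])
}

#' Export a region map as BED
#'
#' Writes the five regions as 0-based half-open BED intervals with the
#' region name in the name column.
#'
#' @param map a [region_map()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_region_bed <- function(map, path) {
  bed <- data.frame(chrom = map$chrom,
                    start = format(map$regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(map$regions$end, scientific = FALSE, trim = TRUE),
                    name = map$regions$region)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write region maps as YAML
#'
#' @param map a [region_map()].
#' @param path file path.
#' @return `write_region_yaml` returns the path invisibly;
#'   `read_region_yaml` returns a [region_map()].
#' @export
write_region_yaml <- function(map, path) {
  obj <- list(chrom = map$chrom,
              regions = lapply(seq_len(nrow(map$regions)), function(i) {
                r <- map$regions[i, ]
                list(region = r$region, start = r$start, end = r$end)
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_region_yaml
#' @export
read_region_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  regions <- do.call(rbind, lapply(obj$regions, function(r)
    data.frame(region = r$region, start = r$start, end = r$end)))
  region_map(obj$chrom, regions)
}
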