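#' Locus arrangements
#'
#' An arrangement is one haploid description of the locus: an ordered list of
#' oriented region segments. The un-rearranged reference arrangement (`*N`)
#' is `Flank1, Dup1, Int, Dup2, Flank2`, all forward. Carrier (`*Fm`)
#' arrangements duplicate Dup1 and Dup2 (copy number 2 each) around a
#' single-copy Int, consistent with the doubled sequencing coverage observed
#' over the duplicated regions in carriers.
#'
#' Invariants enforced: `Flank1` appears exactly once, first, forward;
#' `Flank2` exactly once, last, forward.
#'
#' @param name scenario label (e.g. `"N"`, `"Fm_2"`, or user-defined).
#' @param segments data.frame with columns `region` and `orient`
#'   (`"+"` forward, `"-"` inverted), one row per segment in order.
#' @return an object of class `arrangement`.
#' @export
arrangement <- function(name, segments) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.data.frame(segments),
            all(c("region", "orient") %in% names(segments)))
  segments <- data.frame(region = as.character(segments$region),
                         orient = as.character(segments$orient))
  if (!all(segments$orient %in% c("+", "-")))
    stop("orient must be '+' or '-'")
  n <- nrow(segments)
  if (n < 1L) stop("arrangement needs at least one segment")
  f1 <- which(segments$region == "Flank1")
  f2 <- which(segments$region == "Flank2")
  if ("Flank1" %in% segments$region &&
      !(identical(f1, 1L) && segments$orient[1] == "+"))
    stop("Flank1 must appear exactly once, first, forward")
  if ("Flank2" %in% segments$region &&
      !(identical(f2, n) && segments$orient[n] == "+"))
    stop("Flank2 must appear exactly once, last, forward")
  structure(list(name = name, segments = segments), class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  toks <- ifelse(x$segments$orient == "-",
                 paste0("inv(", x$segments$region, ")"), x$segments$region)
  cat("<arrangement> *", x$name, ": ", paste(toks, collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in Fm locus arrangements
#'
#' The four candidate arrangements of the locus:
#' \describe{
#'   \item{`N`}{the un-rearranged reference: F1, D1, I, D2, F2.}
#'   \item{`Fm_1`}{F1, D1, inv-D2, inv-Int, inv-D1, D2, F2 — a single
#'     duplication-inversion event placing an inverted (Dup2+Int+Dup1) block
#'     between the native-like outer Dup1 and Dup2 copies.}
#'   \item{`Fm_2`}{F1, D1, inv-D2, D1, I, D2, F2 — the distal half
#'     (D1, I, D2, F2) resembles `N`; the proximal half carries
#'     Dup1 + inverted Dup2.}
#'   \item{`Fm_3`}{F1, D1, I, D2, inv-D1, D2, F2 — the proximal half
#'     resembles `N`.}
#' }
#' All three carrier scenarios have region copy numbers Dup1 = 2, Dup2 = 2,
#' Int = 1 and share the same two novel junctions
#' (A: Dup1.END-Dup2.END, B: Dup1.START-Dup2.START); they differ in which
#' copy contexts each duplicated region occupies.
#'
#' @param name one of `"N"`, `"Fm_1"`, `"Fm_2"`, `"Fm_3"`.
#' @return an [arrangement()].
#' @export
fm_arrangement <- function(name = c("N", "Fm_1", "Fm_2", "Fm_3")) {
  name <- match.arg(name)
  seg <- switch(name,
    N = data.frame(
      region = c("Flank1", "Dup1", "Int", "Dup2", "Flank2"),
      orient = c("+", "+", "+", "+", "+")),
    Fm_1 = data.frame(
      region = c("Flank1", "Dup1", "Dup2", "Int", "Dup1", "Dup2", "Flank2"),
      orient = c("+", "+", "-", "-", "-", "+", "+")),
    Fm_2 = data.frame(
      region = c("Flank1", "Dup1", "Dup2", "Dup1", "Int", "Dup2", "Flank2"),
      orient = c("+", "+", "-", "+", "+", "+", "+")),
    Fm_3 = data.frame(
      region = c("Flank1", "Dup1", "Int", "Dup2", "Dup1", "Dup2", "Flank2"),
      orient = c("+", "+", "+", "+", "-", "+", "+")))
  arrangement(name, seg)
}

#' Region copy numbers of an arrangement
#' @param a an [arrangement()].
#' @return named integer vector of copy counts per region.
#' @export
copy_numbers <- function(a) {
  table_to_vec(table(a$segments$region))
}

table_to_vec <- function(tb) {
  v <- as.integer(tb)
  names(v) <- names(tb)
  v
}

#' Implied sequence length of an arrangement
#' @param a an [arrangement()].
#' @param map a [region_map()] supplying region lengths.
#' @return total length in bp of the haplotype the arrangement describes.
#' @export
arrangement_length <- function(a, map) {
  sum(vapply(a$segments$region, function(r) region_length(map, r),
             numeric(1)))
}

#' Reverse an arrangement
#'
#' Full reversal: reverse segment order and flip every orientation. Reading
#' a haplotype from the other end describes the same molecule, so adjacency
#' enumeration is invariant under this operation.
#'
#' @param a an [arrangement()].
#' @return the reversed segment data.frame (not a validated arrangement:
#'   flanks swap ends).
#' @export
reverse_segments <- function(a) {
  seg <- a$segments[rev(seq_len(nrow(a$segments))), ]
  seg$orient <- ifelse(seg$orient == "+", "-", "+")
  rownames(seg) <- NULL
  seg
}

## --- adjacencies -----------------------------------------------------------

## The right-hand extremity of a segment in haplotype order is the region's
## END if forward, START if inverted; the left-hand extremity is the
## complement. An adjacency is the unordered, canonicalized pair of the two
## region ends that meet between consecutive segments.
seg_right_end <- function(orient) ifelse(orient == "+", "END", "START")
seg_left_end <- function(orient) ifelse(orient == "+", "START", "END")

adjacency_key <- function(r1, e1, r2, e2) {
  a <- paste0(r1, ".", e1)
  b <- paste0(r2, ".", e2)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

adjacencies_of_segments <- function(seg) {
  n <- nrow(seg)
  if (n < 2L) return(character(0))
  i <- seq_len(n - 1L)
  adjacency_key(seg$region[i], seg_right_end(seg$orient[i]),
                seg$region[i + 1L], seg_left_end(seg$orient[i + 1L]))
}

#' Enumerate the adjacencies of an arrangement
#'
#' One adjacency per consecutive segment pair, canonicalized so that an
#' adjacency and its mirror (the same junction read in reverse orientation)
#' are identical. The `novel` flag marks adjacencies absent from the
#' reference arrangement: for `*Fm_2` the novel set is exactly
#' \{Dup1.END--Dup2.END, Dup1.START--Dup2.START\} — the two
#' carrier-specific junctions A and B.
#'
#' @param a an [arrangement()].
#' @param reference the arrangement defining the native adjacency set
#'   (default the `*N` arrangement).
#' @return data.frame with columns `left`, `right` (canonical `region.END`
#'   tokens), `key`, and logical `novel`.
#' @export
enumerate_adjacencies <- function(a, reference = fm_arrangement("N")) {
  keys <- unique(adjacencies_of_segments(a$segments))
  native <- unique(adjacencies_of_segments(reference$segments))
  parts <- strsplit(keys, "--", fixed = TRUE)
  data.frame(left = vapply(parts, `[`, character(1), 1L),
             right = vapply(parts, `[`, character(1), 2L),
             key = keys,
             novel = !(keys %in% native))
}

## --- copy contexts ---------------------------------------------------------

flip_orient <- function(o) ifelse(o == "+", "-", "+")

#' Copy contexts of a region within an arrangement
#'
#' One context per occurrence of the region, in arrangement order. Each
#' context records the left and right neighbours (region + orientation)
#' canonicalized to the copy-forward reading frame: a copy and the
#' reverse-complement reading of that copy yield the same context. A
#' neighbour of `NA` marks the locus boundary.
#'
#' For `*Fm_2`, Dup1 has contexts (Flank1+ | Dup2-) and (Dup2- | Int+);
#' Dup2 has (Int+ | Flank2+) and (Dup1- | Dup1-) — the inverted interior
#' copy flanked by the two forward Dup1 copies.
#'
#' @param a an [arrangement()].
#' @param region region name; absent region gives a zero-row result.
#' @return data.frame with columns `region`, `copy`, `copy_orient`,
#'   `left_region`, `left_orient`, `right_region`, `right_orient`.
#' @export
copy_contexts <- function(a, region) {
  seg <- a$segments
  idx <- which(seg$region == region)
  out <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    left <- if (i > 1L) c(seg$region[i - 1L], seg$orient[i - 1L]) else c(NA, NA)
    right <- if (i < nrow(seg)) c(seg$region[i + 1L], seg$orient[i + 1L]) else c(NA, NA)
    if (seg$orient[i] == "-") {
      tmp <- left
      left <- c(right[1], flip_orient(right[2]))
      right <- c(tmp[1], flip_orient(tmp[2]))
    }
    data.frame(region = region, copy = k, copy_orient = seg$orient[i],
               left_region = left[1], left_orient = left[2],
               right_region = right[1], right_orient = right[2])
  })
  if (!length(out))
    return(data.frame(region = character(0), copy = integer(0),
                      copy_orient = character(0),
                      left_region = character(0), left_orient = character(0),
                      right_region = character(0), right_orient = character(0)))
  do.call(rbind, out)
}

#' All copy contexts of an arrangement
#' @param a an [arrangement()].
#' @param regions regions to include (default the duplicated-region names
#'   present in the arrangement).
#' @return data.frame as in [copy_contexts()], rows over all regions.
#' @export
all_copy_contexts <- function(a, regions = unique(a$segments$region)) {
  do.call(rbind, lapply(regions, function(r) copy_contexts(a, r)))
}

context_key <- function(ctx) {
  paste(ctx$region,
        paste0(ifelse(is.na(ctx$left_region), ".", ctx$left_region),
               ifelse(is.na(ctx$left_orient), "", ctx$left_orient)),
        paste0(ifelse(is.na(ctx$right_region), ".", ctx$right_region),
               ifelse(is.na(ctx$right_orient), "", ctx$right_orient)),
        sep = "|")
}

## Does observed context `o` (possibly with NA = unanchored sides) match
## candidate copy context `cc`? NA observed sides match anything.
context_matches <- function(o, cc) {
  if (o$region != cc$region) return(FALSE)
  ok_left <- is.na(o$left_region) ||
    (identical(o$left_region, cc$left_region) &&
       identical(o$left_orient, cc$left_orient))
  ok_right <- is.na(o$right_region) ||
    (identical(o$right_region, cc$right_region) &&
       identical(o$right_orient, cc$right_orient))
  ok_left && ok_right
}

#' Test candidate arrangements against observed haplotype contexts
#'
#' A candidate is consistent iff every observed context equals some copy
#' context of that candidate (canonical comparison; unanchored sides, coded
#' `NA`, match anything). Verdicts are independent across candidates. An
#' empty observation set leaves every candidate consistent and flags the
#' result uninformative.
#'
#' Observing the `*Fm_2` Dup1 contexts (Flank1 | inv-Dup2) and
#' (inv-Dup2 | Int) rules out `*Fm_3` but not `*Fm_1`; adding the Dup2
#' contexts (Int | Flank2) and (Dup1 | Dup1) leaves only `*Fm_2`.
#'
#' @param observed data.frame of anchored haplotype contexts with columns
#'   `region`, `left_region`, `left_orient`, `right_region`, `right_orient`
#'   (as produced by [anchor_haplotypes()] or [copy_contexts()]).
#' @param candidates list of [arrangement()]s.
#' @return data.frame with columns `candidate`, `consistent`,
#'   `n_matched`, `violated` (semicolon-joined keys of unmatched observed
#'   contexts), plus attribute `uninformative`.
#' @export
scenario_consistency <- function(observed, candidates) {
  stopifnot(is.list(candidates))
  uninformative <- is.null(observed) || nrow(observed) == 0L
  res <- lapply(candidates, function(cand) {
    ctxs <- all_copy_contexts(cand)
    if (uninformative) {
      return(data.frame(candidate = cand$name, consistent = TRUE,
                        n_matched = 0L, violated = ""))
    }
    ok <- vapply(seq_len(nrow(observed)), function(i) {
      o <- observed[i, ]
      any(vapply(seq_len(nrow(ctxs)), function(j)
        context_matches(o, ctxs[j, ]), logical(1)))
    }, logical(1))
    data.frame(candidate = cand$name, consistent = all(ok),
               n_matched = sum(ok),
               violated = paste(context_key(observed[!ok, , drop = FALSE]),
                                collapse = ";"))
  })
  out <- do.call(rbind, res)
  attr(out, "uninformative") <- uninformative
  out
}

#' Infer a diploid locus genotype from observed contexts
#'
#' A diploid sample exposes the union of the copy contexts of its two locus
#' haplotypes, so genotype inference tests unordered arrangement pairs: a
#' pair is consistent iff every observed context matches some context of the
#' pair's union AND every context of the union is observed (set equality;
#' unanchored observed sides match permissively). The completeness condition
#' is what separates e.g. `Fm_2/Fm_2` from `Fm_2/N` — a true heterozygote
#' must also show the native contexts of its `*N` chromosome.
#'
#' @inheritParams scenario_consistency
#' @param regions regions whose contexts are compared (default the regions
#'   appearing in `observed`).
#' @return data.frame with columns `hap1`, `hap2`, `consistent`; attribute
#'   `uninformative` as in [scenario_consistency()].
#' @export
infer_genotype <- function(observed, candidates,
                           regions = unique(observed$region)) {
  uninformative <- is.null(observed) || nrow(observed) == 0L
  nm <- vapply(candidates, function(a) a$name, character(1))
  pairs <- which(upper.tri(diag(length(candidates)), diag = TRUE),
                 arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    un <- rbind(all_copy_contexts(candidates[[i]], regions),
                all_copy_contexts(candidates[[j]], regions))
    un <- un[!duplicated(context_key(un)), , drop = FALSE]
    if (uninformative)
      return(data.frame(hap1 = nm[i], hap2 = nm[j], consistent = TRUE))
    obs_ok <- vapply(seq_len(nrow(observed)), function(oi)
      any(vapply(seq_len(nrow(un)), function(ui)
        context_matches(observed[oi, ], un[ui, ]), logical(1))), logical(1))
    un_ok <- vapply(seq_len(nrow(un)), function(ui)
      any(vapply(seq_len(nrow(observed)), function(oi)
        context_matches(observed[oi, ], un[ui, ]), logical(1))), logical(1))
    data.frame(hap1 = nm[i], hap2 = nm[j],
               consistent = all(obs_ok) && all(un_ok))
  })
  out <- do.call(rbind, res)
  attr(out, "uninformative") <- uninformative
  out
}

#' Read / write arrangements as YAML
#' @param a an [arrangement()].
#' @param path file path.
#' @return `write_arrangement_yaml` returns the path invisibly;
#'   `read_arrangement_yaml` returns an [arrangement()].
#' @export
write_arrangement_yaml <- function(a, path) {
  yaml::write_yaml(list(name = a$name,
                        segments = lapply(seq_len(nrow(a$segments)), function(i)
                          list(region = a$segments$region[i],
                               orient = a$segments$orient[i]))), path)
  invisible(path)
}

#' @rdname write_arrangement_yaml
#' @export
read_arrangement_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(obj$segments, function(s)
    data.frame(region = s$region, orient = s$orient)))
  arrangement(obj$name, seg)
}
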