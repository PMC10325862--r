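#' Phase one duplicated region from long-read alignments
#'
#' Convenience wrapper over the phasing chain: pileup over the region,
#' candidate het-site calling, pass labeling, automatic seed selection and
#' haplotype extension.
#'
#' @param aln alignment-block data.frame (with `bases`).
#' @param map a [region_map()].
#' @param region duplicated region to phase.
#' @param min_allele_reads per-allele support for het-site calling.
#' @param min_pair_reads per-haplotype support for extension steps.
#' @param max_noise_frac noise ceiling for extension steps.
#' @param seed_pos seed site (default automatic, [select_seed_site()]).
#' @return list: `phased` ([extend_haplotypes()]), `labels`, `het`
#'   (het-site call result), `counts`.
#' @export
phase_region <- function(aln, map, region, min_allele_reads = 10,
                         min_pair_reads = 5, max_noise_frac = 0.2,
                         seed_pos = NULL) {
  r <- region_row(map, region)
  counts <- pileup_counts(aln, c(r$start, r$end))
  het <- call_het_sites(counts, min_allele_reads)
  if (!nrow(het$sites))
    return(list(phased = NULL, labels = NULL, het = het, counts = counts))
  labels <- label_reads(aln, het$sites)
  if (!is.null(seed_pos)) {
    phased <- extend_haplotypes(labels, het$sites, seed_pos,
                                min_pair_reads, max_noise_frac,
                                region = region)
    return(list(phased = phased, labels = labels, het = het,
                counts = counts))
  }
  ## automatic seeding: a seed on a spurious (error-pile) site yields a
  ## stub chain, so retry from alternative seeds and keep the longest
  tried <- numeric(0)
  phased <- NULL
  for (attempt in 1:4) {
    sp <- tryCatch(select_seed_site(labels, het$sites, aln, map, region,
                                    min_pair_reads, exclude = tried),
                   error = function(e) NULL)
    if (is.null(sp)) break
    tried <- c(tried, sp)
    cand <- extend_haplotypes(labels, het$sites, sp, min_pair_reads,
                              max_noise_frac, region = region)
    if (is.null(phased) || nrow(cand$sites) > nrow(phased$sites))
      phased <- cand
    if (nrow(phased$sites) >= 0.5 * nrow(het$sites)) break
  }
  list(phased = phased, labels = labels, het = het, counts = counts)
}

#' Resolve the locus arrangement of a sample from long-read alignments
#'
#' Runs the full inference chain: block labeling, junction-read
#' classification, per-duplicated-region phasing and anchoring, and
#' scenario/genotype consistency against the candidate arrangements.
#'
#' @param aln alignment-block data.frame.
#' @param map a [region_map()].
#' @param candidates list of candidate [arrangement()]s (default the four
#'   built-ins).
#' @param regions duplicated regions to phase.
#' @param min_allele_reads,min_pair_reads,max_noise_frac phasing
#'   parameters (see [phase_region()]).
#' @param end_tolerance junction/anchor border tolerance in bp.
#' @return list: `contexts` (observed anchored contexts), `scenarios`
#'   ([scenario_consistency()] verdicts), `genotypes`
#'   ([infer_genotype()] verdicts), `junctions` (support table),
#'   `phasing` (per-region [phase_region()] results).
#' @export
resolve_locus <- function(aln, map,
                          candidates = lapply(c("N", "Fm_1", "Fm_2", "Fm_3"),
                                              fm_arrangement),
                          regions = c("Dup1", "Dup2"),
                          min_allele_reads = 10, min_pair_reads = 5,
                          max_noise_frac = 0.2, end_tolerance = 100) {
  if (!"region" %in% names(aln)) aln <- assign_blocks(aln, map)
  jc <- classify_junctions(aln, map, end_tolerance)
  support <- junction_support_table(jc)
  phasing <- list()
  contexts <- list()
  for (reg in regions) {
    ph <- phase_region(aln, map, reg, min_allele_reads, min_pair_reads,
                       max_noise_frac)
    phasing[[reg]] <- ph
    if (!is.null(ph$phased))
      contexts[[reg]] <- anchor_haplotypes(ph$phased, ph$labels, aln, map,
                                           min_support = min_pair_reads,
                                           end_tolerance = end_tolerance)
  }
  obs <- if (length(contexts)) do.call(rbind, contexts) else NULL
  if (!is.null(obs)) rownames(obs) <- NULL
  list(contexts = obs,
       scenarios = scenario_consistency(obs, candidates),
       genotypes = infer_genotype(obs, candidates),
       junctions = support,
       phasing = phasing)
}

#' Switch errors of a phased region against the simulation truth
#'
#' Matches the phased chain to the two planted allele classes: at each
#' haplotype-defining site, haplotype A carries either class 1 or class 2;
#' a switch error is an adjacent site pair where that assignment flips.
#' Sites matching neither class are counted as mismatches.
#'
#' @param phased a [extend_haplotypes()] result.
#' @param truth the `truth` element of [simulate_locus_sample()].
#' @return list: `n_sites`, `switches`, `mismatches`.
#' @export
switch_errors <- function(phased, truth) {
  ch <- phased$sites
  ts <- truth$sites[match(ch$pos, truth$sites$pos), ]
  a1 <- ch$hapA == ts$class1 & ch$hapB == ts$class2
  a2 <- ch$hapA == ts$class2 & ch$hapB == ts$class1
  mism <- sum(!(a1 | a2), na.rm = TRUE) + sum(is.na(ts$pos))
  assign <- ifelse(a1, 1L, ifelse(a2, 2L, NA_integer_))
  assign <- assign[!is.na(assign)]
  switches <- if (length(assign) > 1) sum(diff(assign) != 0) else 0L
  list(n_sites = nrow(ch), switches = switches, mismatches = mism)
}

#' Simulate a sample and recover its generating arrangement
#'
#' End-to-end check used by the validation suite: simulate under a seed,
#' run [resolve_locus()], and compare the consistent genotype pair with
#' the generating pair.
#'
#' @param cfg a [sim_config()].
#' @param candidates candidate arrangements.
#' @return list: `correct` (exactly the generating genotype consistent),
#'   `genotypes`, `contexts`, `truth_pair`, `sim`, `resolved`.
#' @export
recover_scenario <- function(cfg,
                             candidates = lapply(c("N", "Fm_1", "Fm_2",
                                                   "Fm_3"),
                                                 fm_arrangement)) {
  sim <- simulate_locus_sample(cfg, short = FALSE)
  aln <- assign_blocks(sim$long$alignments, cfg$map)
  ## coverage scan over the same alignments (case-only evidence; the
  ## genotype verdict itself rests on junctions + phased anchors)
  cov <- window_coverage(aln, map_span(cfg$map))
  boundaries <- suppressWarnings(detect_boundaries(cov))
  res <- resolve_locus(aln, cfg$map, candidates)
  res$coverage <- cov
  res$boundaries <- boundaries
  res$carrier <- classify_carrier(cov, res$junctions, cfg$map)
  truth_pair <- sort(vapply(cfg$arrangements, function(a) a$name,
                            character(1)))
  g <- res$genotypes
  hit <- g[g$consistent, , drop = FALSE]
  correct <- nrow(hit) == 1L &&
    identical(sort(c(hit$hap1, hit$hap2)), truth_pair)
  list(correct = correct, genotypes = g, contexts = res$contexts,
       truth_pair = truth_pair, sim = sim, resolved = res)
}
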