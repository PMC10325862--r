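test_that("pileup counts bases per position and keeps ambiguity in depth", {
  ## 3 error-free passes over a 10 bp interval plus one with an N
  aln <- rbind(toy_block("r1", 101, 110, bases = "ACGTACGTAC"),
               toy_block("r2", 101, 110, bases = "ACGTACGTAC"),
               toy_block("r3", 105, 110, bases = "ACGTAC"),
               toy_block("r4", 101, 105, bases = "ACGTN"))
  pc <- pileup_counts(aln, c(101, 110))
  expect_equal(pc$A[1], 3L)  # r1, r2, r4
  expect_equal(pc$A[5], 3L)  # r1, r2, r3 carry A; r4 has N
  expect_equal(pc$depth[5], 4L)
  expect_gte(min(pc$depth - (pc$A + pc$C + pc$G + pc$T)), 0)
  ## zero-coverage positions are emitted with zero counts
  pc2 <- pileup_counts(aln, c(95, 100))
  expect_equal(sum(pc2$depth), 0)
})

test_that("het-site calling keeps biallelic sites and rejects tri-allelic ones", {
  counts <- data.frame(pos = 1:4,
                       A = c(15, 15, 15, 40),
                       C = c(1, 10, 0, 0),
                       G = c(12, 12, 9, 0),
                       T = c(0, 0, 0, 0),
                       depth = c(28, 37, 24, 40))
  h <- call_het_sites(counts, min_allele_reads = 10)
  expect_equal(h$sites$pos, 1)  # pos 2 is tri-allelic, 3/4 fail support
  expect_equal(h$sites$allele1, "A")
  expect_equal(h$sites$allele2, "G")
  expect_equal(h$triallelic$pos, 2)
  ## pos 3: second allele below threshold; pos 4: monomorphic
  expect_false(3 %in% h$sites$pos)
  expect_false(4 %in% h$sites$pos)
})

test_that("pair matrices count co-occurrences exactly", {
  mk <- function(id, b1, b2) {
    toy_block(id, 100, 200, bases = paste0(b1, strrep("A", 99), b2))
  }
  aln <- do.call(rbind, c(
    lapply(1:6, function(i) mk(paste0("x", i), "A", "C")),
    lapply(1:5, function(i) mk(paste0("y", i), "T", "G")),
    list(mk("z", "A", "G"))))
  sites <- data.frame(pos = c(100, 200))
  lab <- label_reads(aln, sites)
  m <- pair_matrix(lab, 100, 200)
  expect_equal(m["A", "C"], 6)
  expect_equal(m["T", "G"], 5)
  expect_equal(m["A", "G"], 1)
  expect_equal(sum(m), 12)
  ## disjoint coverage gives an all-zero matrix
  aln2 <- rbind(toy_block("p", 100, 120), toy_block("q", 180, 200))
  lab2 <- label_reads(aln2, sites)
  expect_equal(sum(pair_matrix(lab2, 100, 200)), 0)
  ## every covering pass lands in exactly one base set per site
  sets <- site_read_sets(lab, 100)
  expect_equal(sort(unlist(sets, use.names = FALSE)),
               sort(unique(aln$read_id)))
})

test_that("haplotype extension walks a constructed region and breaks on unlinkable gaps", {
  ## 12 passes, two haplotypes over sites 100/200/300: AAA vs TTT
  mk <- function(id, b, from, to) {
    offs <- c(100, 200, 300)
    keep <- offs >= from & offs <= to
    bas <- strrep("C", to - from + 1)
    for (p in offs[keep])
      substr(bas, p - from + 1, p - from + 1) <- b
    toy_block(id, from, to, bases = bas)
  }
  aln <- do.call(rbind, c(
    lapply(1:6, function(i) mk(paste0("h1_", i), "A", 90, 310)),
    lapply(1:6, function(i) mk(paste0("h2_", i), "T", 90, 310))))
  counts <- pileup_counts(aln, c(90, 310))
  het <- call_het_sites(counts, min_allele_reads = 5)
  expect_equal(het$sites$pos, c(100, 200, 300))
  lab <- label_reads(aln, het$sites)
  ph <- extend_haplotypes(lab, het$sites, 100, min_pair_reads = 5)
  expect_equal(ph$sites$pos, c(100, 200, 300))
  expect_equal(ph$sites$hapA, c("A", "A", "A"))
  expect_equal(ph$sites$hapB, c("T", "T", "T"))
  expect_false(ph$broken_right)
  ## split the reads so no pass covers both 200 and 300: chain breaks
  aln2 <- do.call(rbind, c(
    lapply(1:6, function(i) mk(paste0("h1_", i), "A", 90, 250)),
    lapply(1:6, function(i) mk(paste0("h2_", i), "T", 90, 250)),
    lapply(1:6, function(i) mk(paste0("h3_", i), "A", 260, 310)),
    lapply(1:6, function(i) mk(paste0("h4_", i), "T", 260, 310))))
  lab2 <- label_reads(aln2, het$sites)
  ph2 <- extend_haplotypes(lab2, het$sites, 100, min_pair_reads = 5)
  expect_equal(max(ph2$sites$pos), 200)
  expect_true(ph2$broken_right)
  ## a non-het seed errors
  expect_error(extend_haplotypes(lab, het$sites, 123), "seed")
})

test_that("phasing separates the two copies of each duplicated region with zero switch errors", {
  sim <- fix_fm2_hom()
  aln <- fix_fm2_labeled()
  map <- sim$config$map
  for (reg in c("Dup1", "Dup2")) {
    ph <- phase_region(aln, map, reg)
    expect_false(is.null(ph$phased))
    se <- switch_errors(ph$phased, sim$truth)
    expect_equal(se$switches, 0)
    expect_equal(se$mismatches, 0)
    ## chain spans the region: terminal defining sites near both borders
    r <- region_row(map, reg)
    expect_false(ph$phased$broken_left)
    expect_false(ph$phased$broken_right)
    ## candidate het density tracks the planted ~1%
    dens <- nrow(ph$het$sites) / region_length(map, reg)
    expect_gt(dens, 0.005); expect_lt(dens, 0.015)
  }
})

test_that("phasing output is invariant to read input order", {
  sim <- fix_fm2_hom()
  map <- sim$config$map
  aln <- sim$long$alignments
  set.seed(31)
  perm <- aln[sample(nrow(aln)), ]
  ph1 <- phase_region(assign_blocks(aln, map), map, "Dup1")
  ph2 <- phase_region(assign_blocks(perm, map), map, "Dup1")
  expect_equal(ph1$phased$sites, ph2$phased$sites)
  expect_equal(ph1$phased$seed, ph2$phased$seed)
})

test_that("anchoring recovers the copy contexts of the generating arrangement", {
  sim <- fix_fm2_hom()
  aln <- fix_fm2_labeled()
  map <- sim$config$map
  res <- resolve_locus(aln, map)
  ctx <- res$contexts
  d1 <- ctx[ctx$region == "Dup1", ]
  expect_setequal(paste(d1$left_region, d1$left_orient, d1$right_region,
                        d1$right_orient),
                  c("Flank1 + Dup2 -", "Dup2 - Int +"))
  d2 <- ctx[ctx$region == "Dup2", ]
  expect_setequal(paste(d2$left_region, d2$left_orient, d2$right_region,
                        d2$right_orient),
                  c("Int + Flank2 +", "Dup1 - Dup1 -"))
  ## *N diploid anchors only in native contexts
  simN <- fix_n_hom()
  alnN <- assign_blocks(simN$long$alignments, map)
  resN <- resolve_locus(alnN, map)
  cn <- resN$contexts
  expect_true(all(cn$left_region[cn$region == "Dup1"] == "Flank1"))
  expect_true(all(cn$right_region[cn$region == "Dup1"] == "Int"))
  expect_true(all(cn$left_orient == "+" & cn$right_orient == "+"))
})

test_that("phased haplotypes export as a PS-tagged VCF", {
  sim <- fix_fm2_hom()
  aln <- fix_fm2_labeled()
  ph <- phase_region(aln, sim$config$map, "Dup1")
  tf <- tempfile(fileext = ".vcf")
  write_phased_vcf(list(ph$phased), sim$config$map$chrom, tf)
  lines <- readLines(tf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(ph$phased$sites))
  expect_true(all(grepl("GT:PS\t0\\|1:", body)))
})
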