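test_that("haplotype construction matches the reference for *N and scales for *Fm_2", {
  map <- region_map_from_lengths()
  set.seed(5)
  genome <- random_genome(map)
  hapN <- build_haplotype_sequence(map, fm_arrangement("N"), genome)
  expect_identical(hapN$seq, genome)
  expect_equal(nrow(hapN$projection), 5)
  hap2 <- build_haplotype_sequence(map, fm_arrangement("Fm_2"), genome)
  expect_equal(nchar(hap2$seq), 2 * 12738 + 2 * 17081 + 41253 + 100000)
  expect_error(build_haplotype_sequence(
    map, arrangement("x", data.frame(region = c("Flank1", "Zed", "Flank2"),
                                     orient = "+")), genome),
    "absent from map")
})

test_that("projection round-trips sample and reference coordinates", {
  map <- region_map_from_lengths()
  set.seed(6)
  genome <- random_genome(map)
  hap <- build_haplotype_sequence(map, fm_arrangement("Fm_2"), genome)
  pos <- sort(sample.int(nchar(hap$seq), 200))
  pr <- project_to_ref(hap, pos)
  for (i in sample(seq_along(pos), 25)) {
    back <- ref_to_sample(hap, pr$ref_pos[i])
    expect_true(pos[i] %in% back$sample_pos)
  }
  ## inverted copies project with reversed orientation and complement bases
  inv_blk <- hap$projection[hap$projection$strand == "-", ][1, ]
  sp <- inv_blk$sample_start
  expect_equal(project_to_ref(hap, sp)$ref_pos, inv_blk$ref_end)
})

test_that("planted het-site counts follow the configured density", {
  ## density 0.01 over the scaled Dup1 gives ~127 sites (binomial)
  for (seed in 301:305) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_locus_sample(cfg, long = FALSE, short = FALSE)
    n_d1 <- sum(sim$truth$sites$region == "Dup1")
    expect_lt(abs(n_d1 - 127.38), 3 * sqrt(127) + 1)
  }
  ## density 0 plants nothing
  cfg0 <- sim_config(seed = 1, het_density_dup = 0, het_density_bg = 0)
  sim0 <- simulate_locus_sample(cfg0, long = FALSE, short = FALSE)
  expect_equal(nrow(sim0$truth$sites), 0)
})

test_that("the two copies of a duplicated region carry different planted alleles", {
  sim <- fix_fm2_hom()
  s <- sim$truth$sites[sim$truth$sites$type == "dup", ]
  expect_true(all(s$class1 != s$class2))
  ## copy-aware assignment: both chromosomes of the homozygote share it
  a <- sim$truth$assignment
  expect_equal(sort(unique(a$class)), c(1L, 2L))
  expect_equal(a$class[a$chrom == 1], a$class[a$chrom == 2])
  ## and the planted allele is recoverable per instance, breakpoints too
  inst <- truth_instance_alleles(sim$truth)
  expect_true(all(inst$allele %in% c("A", "C", "G", "T")))
  expect_equal(sim$truth$breakpoints$rise[1],
               region_row(sim$config$map, "Dup1")$start)
})

test_that("long reads hit the depth target and respect the error model", {
  sim <- fix_fm2_hom()
  L <- sum(nchar(sim$dip[[1]]$seq), nchar(sim$dip[[2]]$seq)) / 2
  achieved <- sum(sim$long$reads$read_len) / (2 * L)
  expect_lt(abs(achieved - sim$config$long_read$depth / 2) /
              (sim$config$long_read$depth / 2), 0.1)
  ## error-free *N reads reproduce the reference exactly
  cfg <- sim_config(seed = 401, arrangements = c("N", "N"),
                    long_read = list(depth = 5, error_rate = 0),
                    het_density_dup = 0, het_density_bg = 0)
  simN <- simulate_locus_sample(cfg, short = FALSE)
  a <- simN$long$alignments
  same <- vapply(seq_len(nrow(a)), function(i)
    substr(simN$genome, a$ref_start[i], a$ref_end[i]) == a$bases[i],
    logical(1))
  expect_true(all(same))
  ## reject a degenerate length distribution
  expect_error(sim_config(long_read = list(meanlog = log(20))), "50 bp")
})

test_that("junction-crossing reads split with the correct orientation", {
  sim <- fix_fm2_hom()
  aln <- sim$long$alignments
  d1 <- region_row(sim$config$map, "Dup1")
  d2 <- region_row(sim$config$map, "Dup2")
  ## find reads with a forward block ending at Dup1.END and a mate block
  ## ending at Dup2.END on the minus strand (junction A geometry)
  ids_f <- unique(aln$read_id[aln$strand == "+" & aln$ref_end == d1$end])
  ids_r <- unique(aln$read_id[aln$strand == "-" & aln$ref_end == d2$end])
  expect_gt(length(intersect(ids_f, ids_r)), 0)
  ## reads wholly inside one segment copy stay single-block
  single <- names(which(table(aln$read_id) == 1))
  blk <- aln[aln$read_id %in% single, ]
  expect_true(all(blk$read_start == 1 & blk$read_end == blk$read_len))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77, long_read = list(depth = 10),
                    short_read = list(depth = 5))
  s1 <- simulate_locus_sample(cfg)
  s2 <- simulate_locus_sample(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$long, s2$long)
  expect_identical(s1$short, s2$short)
  expect_identical(s1$truth, s2$truth)
})

test_that("SAM round trip reconstructs every alignment block exactly", {
  sim <- fix_fm2_hom()
  tf <- tempfile(fileext = ".sam")
  write_sam(sim$long, tf, ref_name = sim$config$map$chrom,
            ref_len = map_span(sim$config$map)[2])
  back <- read_long_alignments(tf)
  a <- sim$long$alignments
  a <- a[order(a$read_id, a$read_start), ]
  b <- back[order(back$read_id, back$read_start), ]
  expect_equal(nrow(a), nrow(b))
  for (col in c("ref_start", "ref_end", "strand", "read_start",
                "read_end", "read_len", "bases"))
    expect_equal(unname(a[[col]]), unname(b[[col]]), label = col)
})

test_that("short-read depth reflects carrier copy number", {
  map <- region_map_from_lengths()
  d1 <- region_row(map, "Dup1")
  mean_depth <- function(sim, from, to)
    mean(sim$short$depth[(from:to) - sim$short$offset + 1])
  simN <- fix_n_hom()
  expect_lt(abs(mean_depth(simN, 1, 50000) - 30) / 30, 0.1)
  expect_lt(abs(mean_depth(simN, d1$start, d1$end) - 30) / 30, 0.1)
  sim2 <- fix_fm2_hom()
  expect_lt(abs(mean_depth(sim2, d1$start, d1$end) - 60) / 60, 0.1)
  het <- fix_fm2_het()
  expect_lt(abs(mean_depth(het, d1$start, d1$end) - 45) / 45, 0.1)
})

test_that("aligned-base totals conserve depth times mean copy number", {
  sim <- fix_fm2_hom()
  span <- map_span(sim$config$map)
  ref_len <- span[2] - span[1] + 1
  sample_len <- nchar(sim$dip[[1]]$seq)
  expected <- sim$config$long_read$depth * sample_len / ref_len
  got <- sum(sim$long$alignments$ref_end -
               sim$long$alignments$ref_start + 1) / ref_len
  expect_lt(abs(got - expected) / expected, 0.05)
})
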