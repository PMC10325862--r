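map_scaled <- region_map_from_lengths()

test_that("block labeling follows the majority-overlap rule with a size floor", {
  m <- map_scaled
  int <- region_row(m, "Int"); d2 <- region_row(m, "Dup2")
  ## block fully inside Dup1
  b1 <- assign_blocks(toy_block("r", 51000, 52000), m)
  expect_equal(b1$region, "Dup1")
  expect_true(b1$region_confident)
  ## 10 kb block 85% in Int, 15% in Dup2: labeled Int
  st <- int$end - 8499
  b2 <- assign_blocks(toy_block("r", st, st + 9999), m)
  expect_equal(b2$region, "Int")
  expect_true(b2$region_confident)  # 85% >= 80%
  ## 150 bp block stays unlabeled
  b3 <- assign_blocks(toy_block("r", 51000, 51149), m)
  expect_true(is.na(b3$region))
  ## straddling block below the confident fraction keeps majority label
  st2 <- int$end - 3999
  b4 <- assign_blocks(toy_block("r", st2, st2 + 9999), m)  # 40% Int, 60% Dup2
  expect_equal(b4$region, "Dup2")
  expect_false(b4$region_confident)
})

test_that("spanning-read search separates junction reads from native neighbours", {
  sim <- fix_fm2_hom()
  aln <- fix_fm2_labeled()
  sp <- find_spanning_reads(aln, sim$config$map)
  expect_gt(length(unique(sp$read_id)), 0)
  expect_false(attr(sp, "adjacent_pair"))
  ## *N simulation has no Dup1--Dup2 junction reads (long native
  ## traversals through the 41 kb Int can exist but classify as native)
  simN <- fix_n_hom()
  alnN <- assign_blocks(simN$long$alignments, simN$config$map)
  jN <- classify_junctions(alnN, simN$config$map)
  tabN <- junction_support_table(jN)
  expect_equal(unname(tabN[c("A", "B")]), c(0L, 0L))
  ## a Flank1+Dup1 read is excluded from the Dup1--Dup2 list
  fb <- assign_blocks(toy_block("r", 49000, 51000), sim$config$map)
  expect_equal(nrow(find_spanning_reads(fb, sim$config$map)), 0)
  expect_gt(nrow(find_spanning_reads(fb, sim$config$map,
                                     c("Flank1", "Dup1"))), 0)
  expect_true(attr(find_spanning_reads(fb, sim$config$map,
                                       c("Flank1", "Dup1")),
                   "adjacent_pair"))
})

test_that("the orientation grammar classifies constructed junction reads", {
  m <- map_scaled
  d1 <- region_row(m, "Dup1"); d2 <- region_row(m, "Dup2")
  ## junction A: forward Dup1 arm to its END, reverse Dup2 arm to its END
  a_read <- rbind(
    toy_block("a", d1$end - 999, d1$end, "+", read_start = 1,
              read_len = 2000),
    toy_block("a", d2$end - 999, d2$end, "-", read_start = 1001,
              read_len = 2000))
  a_read$primary <- c(TRUE, FALSE)
  ja <- classify_junction(assign_blocks(a_read, m), m)
  expect_equal(ja$type, "A")
  expect_match(ja$signature, "DUP1-END\\|END-DUP2")
  ## junction B: reverse Dup1 arm from its START, forward Dup2 from START
  b_read <- rbind(
    toy_block("b", d1$start, d1$start + 999, "-", read_start = 1,
              read_len = 2000),
    toy_block("b", d2$start, d2$start + 999, "+", read_start = 1001,
              read_len = 2000))
  b_read$primary <- c(TRUE, FALSE)
  jb <- classify_junction(assign_blocks(b_read, m), m)
  expect_equal(jb$type, "B")
  ## endpoints far from any border: unclassified with a reason
  u_read <- rbind(
    toy_block("u", d1$start + 3000, d1$start + 3999, "+", read_start = 1,
              read_len = 2000),
    toy_block("u", d2$start + 3000, d2$start + 3999, "-",
              read_start = 1001, read_len = 2000))
  ju <- classify_junction(assign_blocks(u_read, m), m)
  expect_equal(ju$type, "unclassified")
  expect_match(ju$reason, "border")
})

test_that("junction calls are invariant under reversing the read", {
  sim <- fix_fm2_hom()
  m <- sim$config$map
  aln <- fix_fm2_labeled()
  sp <- find_spanning_reads(aln, m)
  ids <- unique(sp$read_id)
  set.seed(13)
  ids <- sample(ids, min(30, length(ids)))
  for (id in ids) {
    blocks <- sp[sp$read_id == id, ]
    fwd <- classify_junction(blocks, m)
    rev <- classify_junction(assign_blocks(reverse_read_blocks(blocks), m), m)
    expect_setequal(fwd$type, rev$type)
  }
})

test_that("classified junction calls match the generating adjacency, and tighter tolerance never adds calls", {
  counts <- sapply(c(501, 502, 503, 504, 505), function(seed) {
    cfg <- sim_config(seed = seed, long_read = list(depth = 30))
    sim <- simulate_locus_sample(cfg, short = FALSE)
    aln <- assign_blocks(sim$long$alignments, cfg$map)
    jc <- classify_junctions(aln, cfg$map)
    ## every A/B call's read must truly cross the corresponding junction:
    ## in the truth, A-reads have a -strand block ending at Dup2.END etc.
    d1 <- region_row(cfg$map, "Dup1"); d2 <- region_row(cfg$map, "Dup2")
    for (i in which(jc$type == "A")) {
      blk <- aln[aln$read_id == jc$read_id[i], ]
      expect_true(any(abs(blk$ref_end - d1$end) <= 100) &&
                    any(abs(blk$ref_end - d2$end) <= 100))
    }
    for (i in which(jc$type == "B")) {
      blk <- aln[aln$read_id == jc$read_id[i], ]
      expect_true(any(abs(blk$ref_start - d1$start) <= 100) &&
                    any(abs(blk$ref_start - d2$start) <= 100))
    }
    tab <- junction_support_table(jc)
    tab10 <- junction_support_table(classify_junctions(aln, cfg$map,
                                                       end_tolerance = 10))
    expect_lte(tab10[["A"]], tab[["A"]])
    expect_lte(tab10[["B"]], tab[["B"]])
    expect_equal(tab[["unclassified"]], 0L)
    tab[c("A", "B")]
  })
  expect_true(all(counts["A", ] >= 1))
  expect_true(all(counts["B", ] >= 1))
})

test_that("a mixed heterozygote shows junction and native support together", {
  het <- fix_fm2_het()
  aln <- assign_blocks(het$long$alignments, het$config$map)
  tab <- junction_support_table(classify_junctions(aln, het$config$map))
  expect_gt(tab[["A"]], 0)
  expect_gt(tab[["B"]], 0)
  expect_gt(tab[["native"]], 0)
})
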