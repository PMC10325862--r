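test_that("region lengths follow the 1-based inclusive convention", {
  m <- fm_region_map()
  expect_equal(region_length(m, "Dup1"), 127380)
  expect_equal(region_length(m, "Dup2"), 170816)
  expect_equal(region_length(m, "Int"), 412534)
  expect_equal(region_length_kb(m, "Dup1"), 127)
  expect_equal(region_length_kb(m, "Int"), 412)
  expect_equal(region_length_kb(m, "Dup2"), 170)
  ## degenerate single-base interval
  m1 <- region_map("c", data.frame(region = c("a", "b"),
                                   start = c(5, 6), end = c(5, 9)))
  expect_equal(region_length(m1, "a"), 1)
  expect_error(region_length(m, "nope"), "unknown region")
})

test_that("region map invariants are enforced", {
  expect_error(region_map("c", data.frame(region = c("a", "b"),
                                          start = c(1, 12),
                                          end = c(10, 20))),
               "contiguous")
  expect_error(region_map("c", data.frame(region = c("a", "b"),
                                          start = c(1, 11),
                                          end = c(10, 5))))
  ## YAML round trip
  m <- fm_region_map()
  tf <- tempfile(fileext = ".yaml")
  write_region_yaml(m, tf)
  expect_equal(read_region_yaml(tf)$regions, m$regions)
})

test_that("arrangement copy numbers match the carrier model", {
  expect_equal(unname(copy_numbers(fm_arrangement("N"))[c("Dup1", "Int", "Dup2")]),
               c(1L, 1L, 1L))
  for (s in c("Fm_1", "Fm_2", "Fm_3")) {
    cn <- copy_numbers(fm_arrangement(s))
    expect_equal(unname(cn[c("Dup1", "Dup2", "Int")]), c(2L, 2L, 1L),
                 label = s)
  }
  expect_error(arrangement("bad", data.frame(region = c("Dup1", "Flank1"),
                                             orient = c("+", "+"))),
               "Flank1")
})

test_that("adjacency enumeration matches a brute-force oracle and flags the two carrier junctions", {
  adjN <- enumerate_adjacencies(fm_arrangement("N"))
  expect_equal(nrow(adjN), 4)
  expect_false(any(adjN$novel))
  for (s in c("Fm_1", "Fm_2", "Fm_3")) {
    adj <- enumerate_adjacencies(fm_arrangement(s))
    expect_setequal(adj$key[adj$novel],
                    c("Dup1.END--Dup2.END", "Dup1.START--Dup2.START"))
  }
  ## single internal inversion of *N creates exactly two novel adjacencies
  inv <- arrangement("inv", data.frame(
    region = c("Flank1", "Dup1", "Int", "Dup2", "Flank2"),
    orient = c("+", "+", "-", "+", "+")))
  expect_equal(sum(enumerate_adjacencies(inv)$novel), 2)
  ## oracle comparison on random arrangements
  set.seed(42)
  for (i in 1:25) {
    a <- random_arrangement()
    expect_setequal(enumerate_adjacencies(a)$key,
                    oracle_adjacencies(a$segments))
  }
})

test_that("adjacencies are invariant under full arrangement reversal", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_arrangement()
    rev_keys <- fmphase:::adjacencies_of_segments(reverse_segments(a))
    expect_setequal(unique(rev_keys), enumerate_adjacencies(a)$key)
  }
})

test_that("copy contexts are canonical and orientation-free", {
  fm2 <- fm_arrangement("Fm_2")
  d1 <- copy_contexts(fm2, "Dup1")
  expect_equal(nrow(d1), 2)
  expect_equal(d1$left_region, c("Flank1", "Dup2"))
  expect_equal(d1$left_orient, c("+", "-"))
  expect_equal(d1$right_region, c("Dup2", "Int"))
  d2 <- copy_contexts(fm2, "Dup2")
  ## the inverted interior copy reads (Dup1- | Dup2 | Dup1-) canonically
  expect_true(any(d2$left_region == "Dup1" & d2$left_orient == "-" &
                    d2$right_region == "Dup1" & d2$right_orient == "-"))
  expect_true(any(d2$left_region == "Int" & d2$right_region == "Flank2"))
  ## single copy in *N; absent region gives an empty frame
  expect_equal(nrow(copy_contexts(fm_arrangement("N"), "Dup1")), 1)
  expect_equal(nrow(copy_contexts(fm_arrangement("N"), "nope")), 0)
})

test_that("scenario consistency reproduces the elimination logic", {
  cands <- lapply(c("N", "Fm_1", "Fm_2", "Fm_3"), fm_arrangement)
  obs_d1 <- copy_contexts(fm_arrangement("Fm_2"), "Dup1")
  v1 <- scenario_consistency(obs_d1, cands)
  expect_equal(v1$consistent, c(FALSE, TRUE, TRUE, FALSE))
  obs_all <- all_copy_contexts(fm_arrangement("Fm_2"), c("Dup1", "Dup2"))
  v2 <- scenario_consistency(obs_all, cands)
  expect_equal(v2$candidate[v2$consistent], "Fm_2")
  obs_n <- all_copy_contexts(fm_arrangement("N"), c("Dup1", "Dup2"))
  v3 <- scenario_consistency(obs_n, cands)
  expect_equal(v3$candidate[v3$consistent], "N")
  ## empty observations: all consistent, flagged uninformative
  v4 <- scenario_consistency(obs_d1[0, ], cands)
  expect_true(all(v4$consistent))
  expect_true(attr(v4, "uninformative"))
})

test_that("every arrangement is consistent with its own contexts", {
  cands <- lapply(c("N", "Fm_1", "Fm_2", "Fm_3"), fm_arrangement)
  set.seed(11)
  for (a in c(cands, lapply(1:10, function(i) random_arrangement()))) {
    obs <- all_copy_contexts(a, intersect(c("Dup1", "Dup2"),
                                          a$segments$region))
    v <- scenario_consistency(obs, list(a))
    expect_true(all(v$consistent), label = a$name)
  }
})

test_that("genotype-pair inference separates homozygote from heterozygote", {
  cands <- lapply(c("N", "Fm_1", "Fm_2", "Fm_3"), fm_arrangement)
  hom <- all_copy_contexts(fm_arrangement("Fm_2"), c("Dup1", "Dup2"))
  g1 <- infer_genotype(hom, cands)
  hit <- g1[g1$consistent, ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$hap1, hit$hap2), c("Fm_2", "Fm_2"))
  het <- unique(rbind(hom, all_copy_contexts(fm_arrangement("N"),
                                             c("Dup1", "Dup2"))))
  g2 <- infer_genotype(het, cands)
  hit2 <- g2[g2$consistent, ]
  expect_equal(nrow(hit2), 1)
  expect_setequal(c(hit2$hap1, hit2$hap2), c("N", "Fm_2"))
})

test_that("arrangement length equals the built haplotype sequence length", {
  map <- region_map_from_lengths()
  set.seed(3)
  genome <- random_genome(map)
  for (s in c("N", "Fm_1", "Fm_2", "Fm_3")) {
    a <- fm_arrangement(s)
    hap <- build_haplotype_sequence(map, a, genome)
    expect_equal(nchar(hap$seq), arrangement_length(a, map), label = s)
  }
})
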