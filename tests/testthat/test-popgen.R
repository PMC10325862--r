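test_that("diversity formulas match their textbook values", {
  ## n=4, S=3 over 100 effective sites: theta_W = 3/((1+1/2+1/3)*100)
  geno <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  panel <- hap_panel(geno, pos = c(10, 50, 90), hap_pop = rep("p", 4))
  d <- diversity_stats(panel, make_windows(100, size = 100))
  expect_equal(d$theta_w, 3 / ((1 + 1 / 2 + 1 / 3) * 100))
  expect_equal(d$S, 3L)
  ## two haplotypes differing at 2 of 100 sites: pi = 0.02
  g2 <- rbind(c(1, 1), c(0, 0))
  p2 <- hap_panel(g2, pos = c(10, 20), hap_pop = rep("p", 2))
  d2 <- diversity_stats(p2, make_windows(100, size = 100))
  expect_equal(d2$pi, 0.02)
  ## when pi-based and Watterson estimates coincide, Tajima's D = 0
  n <- 4; S <- 2
  pi_tot <- S / sum(1 / (1:(n - 1)))
  expect_equal(tajimas_d(S, n, pi_tot), 0)
  ## no segregating sites: undefined, emitted as missing
  expect_true(is.na(tajimas_d(0, 10, 0)))
  expect_true(is.na(fu_li_d_star(0, 10, 0)))
})

test_that("estimators agree with brute-force oracles to 1e-9", {
  set.seed(61)
  for (rep in 1:100) {
    n1 <- 5; n2 <- 5; S <- 200
    geno <- matrix(rbinom((n1 + n2) * S, 1, runif(1, 0.1, 0.5)),
                   nrow = n1 + n2)
    ## ensure polymorphism panel-wide
    fix <- colSums(geno) %in% c(0, n1 + n2)
    geno[1, fix] <- 1L - geno[1, fix]
    pos <- sort(sample.int(10000, S))
    panel <- hap_panel(geno, pos, hap_pop = rep(c("a", "b"), each = 5))
    w <- make_windows(10000, size = 10000)
    d <- diversity_stats(panel, w)
    expect_equal(d$pi * 10000, oracle_pi_total(geno), tolerance = 1e-9)
    expect_equal(d$theta_w, oracle_theta_w(geno, 10000), tolerance = 1e-9)
    f <- differentiation_stats(panel, "a", "b", w)
    expect_equal(f$dxy, oracle_dxy(geno[1:5, ], geno[6:10, ], 10000),
                 tolerance = 1e-9)
    ## per-site Hudson F_ST against direct pairwise loops
    ps <- per_site_fst(panel, "a", "b")
    idx <- sample(nrow(ps), 20)
    for (i in idx) {
      j <- match(ps$pos[i], pos)
      expect_equal(ps$fst[i], oracle_site_fst(geno[1:5, j], geno[6:10, j]),
                   tolerance = 1e-9)
    }
    ## Tajima's D from its definition parts
    expect_equal(d$tajimas_d, tajimas_d(d$S, 10, d$pi * 10000),
                 tolerance = 1e-12)
  }
})

test_that("fixed-difference panels give the boundary F_ST values", {
  geno <- rbind(matrix(0L, 4, 10), matrix(1L, 4, 10))
  panel <- hap_panel(geno, pos = seq(10, 100, by = 10),
                     hap_pop = rep(c("a", "b"), each = 4))
  f <- differentiation_stats(panel, "a", "b", make_windows(100, size = 100))
  expect_equal(f$fst, 1)
  expect_equal(f$dxy, 10 / 100)
  fs <- fixed_sites(panel, "a", "b")
  expect_equal(nrow(fs), 10)
  expect_true(all(fs$fst == 1))
  ## identical populations: F_ST exactly 0 (up to the unbiased correction)
  blockg <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                  c(0L, 0L, 1L))
  p2 <- hap_panel(rbind(blockg, blockg), pos = c(10, 20, 30),
                  hap_pop = rep(c("a", "b"), each = 4))
  f2 <- differentiation_stats(p2, "a", "b", make_windows(30, size = 30))
  ## literal copies give the analytic small-sample value -1/(n-1); negative
  ## estimates are preserved, not clipped
  expect_equal(f2$fst[1], -1 / 3, tolerance = 1e-9)
  expect_equal(nrow(fixed_sites(p2, "a", "b")), 0)
  ## a 0.5/0.5 site is nowhere near fixed
  g3 <- cbind(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
  p3 <- hap_panel(g3, pos = 1, hap_pop = rep(c("a", "b"), each = 4))
  expect_equal(nrow(fixed_sites(p3, "a", "b")), 0)
})

test_that("null and drifted simulations recover their F_ST", {
  sp <- fix_neutral_panel()
  f <- differentiation_stats(sp$panel, "pop1", "pop2")
  expect_lt(abs(mean(f$fst, na.rm = TRUE)), 0.01)
  ## neutral calibration of the frequency-spectrum statistics
  d <- diversity_stats(sp$panel, pop = "pop1")
  expect_lt(abs(mean(d$tajimas_d, na.rm = TRUE)), 0.5)
  expect_lt(abs(mean(d$fu_li_d_star, na.rm = TRUE)), 0.5)
  for (F in c(0.05, 0.16, 0.36)) {
    sim <- simulate_panel(n_pops = 2, haps_per_pop = 18, n_sites = 10000,
                          span = 1e6, drift = F, seed = 700 + round(100 * F))
    fw <- differentiation_stats(sim$panel, "pop1", "pop2")
    expect_lt(abs(mean(fw$fst, na.rm = TRUE) - F), 0.03, label = F)
  }
})

test_that("window filters apply the callability and repeat rules", {
  w <- make_windows(150000, size = 50000)
  callable <- data.frame(start = c(1, 60001), end = c(30000, 150000))
  repeats <- data.frame(start = 110000, end = 120000)
  wf <- window_filters(w, callable, repeats)
  expect_equal(wf$callable_frac, c(0.6, 0.8, 1), tolerance = 1e-6)
  expect_false(wf$pass[1])   # 60% callable < 80%
  expect_true(wf$pass[2])
  expect_false(wf$pass[3])   # >0.1 repeat fraction
  expect_warning(window_filters(w, NULL, repeats), "mask")
  ## masks round-trip through BED
  tf <- tempfile(fileext = ".bed")
  write_mask_bed(callable, tf)
  expect_equal(read_mask_bed(tf), callable)
})

test_that("outlier windows use the empirical quantile and bookended merging", {
  w <- make_windows(1000 * 50000, size = 50000)
  set.seed(71)
  w$fst <- runif(nrow(w))
  w$pass <- TRUE
  out <- outlier_windows(w, "fst", top_frac = 0.01)
  expect_equal(sum(out$n_windows), 10)
  ## three consecutive outliers merge into one interval
  w2 <- w
  w2$fst <- 0
  w2$fst[51:53] <- 1
  w2$fst[200] <- 1
  out2 <- outlier_windows(w2, "fst", top_frac = 0.004)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$n_windows[1], 3)
  expect_equal(out2$end[1] - out2$start[1] + 1, 150000)
  ## too few windows: warns and returns the best one
  expect_warning(best <- outlier_windows(w[1:50, ], "fst", 0.01), "best")
  expect_equal(nrow(best), 1)
})

test_that("private-allele counting honors exclusions and tracks isolation", {
  ## focal {A,T}-like site: focal segregates, others fixed ref
  geno <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L),
                c(0L, 1L), c(0L, 1L))
  panel <- hap_panel(geno, pos = c(5, 9),
                     hap_pop = c("f", "f", "c1", "c1", "c2", "c2"))
  ## site 5: allele 1 private to f; site 9: allele 0 private to f
  expect_equal(private_alleles(panel, "f", c("c1", "c2")), 2)
  expect_equal(private_alleles(panel, "f", c("c1", "c2"),
                               exclude_pos = 5), 1)
  ## identical populations share everything
  g2 <- matrix(rep(c(1L, 0L, 1L, 0L), 3), nrow = 4)
  p2 <- hap_panel(g2, pos = 1:3, hap_pop = c("f", "f", "c", "c"))
  expect_equal(private_alleles(p2, "f", "c"), 0)
  ## private alleles grow with isolation drift
  ## coupled seeds so the only difference between runs is the isolation
  ## level (symmetric drift: both lineages diverge from the ancestor)
  counts <- vapply(c(0.02, 0.15, 0.4), function(F) {
    sim <- simulate_panel(n_pops = 2, haps_per_pop = 10, n_sites = 3000,
                          span = 1e6, drift = c(F, F), seed = 901)
    private_alleles(sim$panel, "pop1", "pop2")
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("panel VCF, population map and masks round-trip", {
  sp <- simulate_panel(n_pops = 2, haps_per_pop = 6, n_sites = 300,
                       span = 1e5, drift = 0.1, seed = 81)
  tf <- tempfile(fileext = ".vcf")
  write_panel_vcf(sp$panel, tf)
  pm <- tempfile(fileext = ".tsv")
  write_pop_map(sp$panel$samples, pm)
  back <- read_panel_vcf(tf, pm)
  expect_identical(back$geno, sp$panel$geno)
  expect_identical(back$pos, sp$panel$pos)
  expect_identical(back$hap_pop, sp$panel$hap_pop)
  ## the gzipped flavour reads identically
  tgz <- tempfile(fileext = ".vcf.gz")
  write_panel_vcf(sp$panel, tgz)
  expect_identical(read_panel_vcf(tgz, pm)$geno, sp$panel$geno)
})
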