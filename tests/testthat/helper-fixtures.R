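## Shared fixtures, memoised so expensive simulations run once per suite.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

fix_fm2_hom <- function() fixture("fm2_hom", function()
  simulate_locus_sample(sim_config(seed = 101)))

fix_n_hom <- function() fixture("n_hom", function()
  simulate_locus_sample(sim_config(seed = 102, arrangements = c("N", "N"))))

fix_fm2_het <- function() fixture("fm2_het", function()
  simulate_locus_sample(sim_config(seed = 103,
                                   arrangements = c("Fm_2", "N"))))

fix_fm2_labeled <- function() fixture("fm2_labeled", function() {
  sim <- fix_fm2_hom()
  assign_blocks(sim$long$alignments, sim$config$map)
})

fix_neutral_panel <- function() fixture("neutral_panel", function()
  simulate_panel(n_pops = 2, haps_per_pop = 18, n_sites = 10000,
                 span = 1e6, drift = 0, seed = 201))

## random arrangement over the five regions (Flank rules respected)
random_arrangement <- function(n_mid = sample(3:6, 1)) {
  mid <- data.frame(region = sample(c("Dup1", "Int", "Dup2"), n_mid,
                                    replace = TRUE),
                    orient = sample(c("+", "-"), n_mid, replace = TRUE))
  arrangement("random", rbind(
    data.frame(region = "Flank1", orient = "+"), mid,
    data.frame(region = "Flank2", orient = "+")))
}

## independent brute-force adjacency oracle: enumerate consecutive-end
## pairs directly and canonicalize by string sort
oracle_adjacencies <- function(seg) {
  n <- nrow(seg)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    right_end <- if (seg$orient[i] == "+") "END" else "START"
    left_end <- if (seg$orient[i + 1] == "+") "START" else "END"
    a <- paste0(seg$region[i], ".", right_end)
    b <- paste0(seg$region[i + 1], ".", left_end)
    out <- c(out, paste(sort(c(a, b)), collapse = "--"))
  }
  unique(out)
}

## reverse-complement reading of a read's alignment blocks
reverse_read_blocks <- function(blocks) {
  L <- blocks$read_len[1]
  rs <- L - blocks$read_end + 1
  re <- L - blocks$read_start + 1
  blocks$read_start <- rs
  blocks$read_end <- re
  blocks$strand <- ifelse(blocks$strand == "+", "-", "+")
  blocks[order(blocks$read_start), ]
}

## brute-force popgen oracles: direct pairwise loops over haplotypes
oracle_pi_total <- function(geno) {
  n <- nrow(geno)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(geno[i, ] != geno[j, ])
  tot / choose(n, 2)
}

oracle_theta_w <- function(geno, eff) {
  n <- nrow(geno)
  cnt <- colSums(geno)
  S <- sum(cnt > 0 & cnt < n)
  S / (sum(1 / seq_len(n - 1)) * eff)
}

oracle_dxy <- function(g1, g2, eff) {
  tot <- 0
  for (i in seq_len(nrow(g1)))
    for (j in seq_len(nrow(g2)))
      tot <- tot + sum(g1[i, ] != g2[j, ])
  tot / (nrow(g1) * nrow(g2)) / eff
}

oracle_site_fst <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  hw <- 0
  for (i in seq_len(n1 - 1)) for (j in (i + 1):n1)
    hw <- hw + (x1[i] != x1[j])
  hw1 <- hw / choose(n1, 2)
  hw <- 0
  for (i in seq_len(n2 - 1)) for (j in (i + 1):n2)
    hw <- hw + (x2[i] != x2[j])
  hw2 <- hw / choose(n2, 2)
  hb <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2))
    hb <- hb + (x1[i] != x2[j])
  hb <- hb / (n1 * n2)
  if (hb == 0) return(NA_real_)
  1 - ((hw1 + hw2) / 2) / hb
}

## toy alignment-block rows for constructed cases
toy_block <- function(read_id, ref_start, ref_end, strand = "+",
                      read_start = 1, read_len = NULL, bases = NULL,
                      primary = TRUE) {
  w <- ref_end - ref_start + 1
  if (is.null(read_len)) read_len <- read_start + w - 1
  if (is.null(bases)) bases <- strrep("A", w)
  data.frame(read_id = read_id, ref = "locus", ref_start = ref_start,
             ref_end = ref_end, strand = strand, read_start = read_start,
             read_end = read_start + w - 1, primary = primary,
             bases = bases, read_len = read_len, hap = NA_integer_)
}
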