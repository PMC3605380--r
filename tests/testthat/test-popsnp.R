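test_that("the mapping acceptance rule is the two-threshold comparison", {
  cfg <- mapping_config(similarity = 0.9, length_fraction = 0.8)
  expect_true(alignment_accepted(95, 100, round(0.93 * 95), cfg))
  expect_false(alignment_accepted(70, 100, 70, cfg))     # length fraction
  expect_false(alignment_accepted(100, 100, 85, cfg))    # similarity
  expect_identical(mapping_preset("initial")$similarity, 0.8)
  expect_identical(mapping_preset("initial")$length_fraction, 0.9)
})

test_that("reads map back to their simulated origin", {
  g <- make_genome(2000, 500, 400, seed = 80)
  s <- genome_sequence(g)
  ## single-copy read at a known position, both orientations
  r <- substr(s, 501, 600)
  al <- map_reads(c(a = r, b = revcomp(r)), s)
  expect_equal(al$pos, c(501, 501))
  expect_setequal(al$strand, c("+", "-"))
  expect_equal(al$matches, c(100L, 100L))
  ## a read across the circular origin still maps
  wrap <- plastidkit:::circular_substr(s, nchar(s) - 49, 100)
  alw <- map_reads(c(w = wrap), s)
  expect_equal(alw$pos, nchar(s) - 49)
  ## unmappable read is dropped
  set.seed(81)
  expect_equal(nrow(map_reads(c(x = rand_dna(100)), s)), 0)
})

test_that("IR-ambiguous reads split between copies under match_mode random", {
  g <- make_genome(2000, 500, 400, seed = 82)
  s <- genome_sequence(g)
  reg <- genome_regions(g)
  r <- substr(s, reg$start[2] + 50, reg$start[2] + 149)  # inside IRb
  al1 <- map_reads(c(r = r), s, mapping_config(seed = 1))
  expect_equal(al1$n_best, 2L)
  picks <- vapply(1:40, function(sd)
    map_reads(c(r = r), s, mapping_config(seed = sd))$pos, 0L)
  irb_frac <- mean(picks == reg$start[2] + 50)
  ## binomial(40, 0.5): 3 SD is about 0.24
  expect_lt(abs(irb_frac - 0.5), 0.25)
  expect_equal(nrow(map_reads(c(r = r), s,
                              mapping_config(match_mode = "unique"))), 0)
})

test_that("pileup and coverage follow their definitions", {
  g <- make_genome(2000, 500, 400, seed = 83)
  s <- genome_sequence(g)
  empty <- plastidkit:::empty_alignments(nchar(s))
  p0 <- pileup(empty, s)
  expect_true(all(p0$depth == 0))
  expect_equal(coverage(empty, s), 0)

  rp <- simulate_reads(make_pool(g, 1, list()),
                       sim_config(n_pairs = round(50 * nchar(s) / 200),
                                  cp_fraction = 1, per_base_error = 0,
                                  seed = 84))
  al <- map_reads(rp, s)
  expect_equal(coverage(al, s), sum(al$aln_len) / nchar(s))
  pi <- pileup(al, s)
  expect_equal(sum(pi$depth), sum(al$aln_len))
  ## mean pileup depth is the nominal coverage within 3 SD
  expect_lt(abs(mean(pi$depth) - 50), 3 * sqrt(50 * 100 / nchar(s)) + 0.5)
  ## error-free reads never contradict the reference
  refcnt <- mapply(function(ref, A, C, G, T) switch(ref, A = A, C = C,
                                                    G = G, T = T),
                   pi$ref, pi$A, pi$C, pi$G, pi$T)
  expect_equal(sum(refcnt), sum(pi$depth))
})

test_that("call_snps equals the literal threshold scan", {
  mk <- function(depths, alts) {
    data.table::data.table(pos = seq_along(depths), ref = "A",
                           depth = depths, A = depths - alts, C = alts,
                           G = 0L, T = 0L, DEL = 0L)
  }
  pile <- mk(c(200L, 200L, 8L), c(50L, 30L, 4L))
  c20 <- call_snps(pile, 0.2, 10)
  expect_equal(c20$pos, 1L)                       # 25% passes, 15% fails
  c10 <- call_snps(pile, 0.1, 10)
  expect_setequal(c10$pos, c(1L, 2L))             # depth 8 never called
  expect_error(call_snps(pile, 0, 10), "mvf")

  set.seed(85)
  for (i in 1:10) {
    n <- 40
    depth <- sample(0:60, n, TRUE)
    counts <- t(vapply(depth, function(d) {
      x <- stats::rmultinom(1, d, c(0.7, 0.1, 0.1, 0.1))[, 1]
      as.integer(x)
    }, integer(4)))
    pile_i <- data.table::data.table(
      pos = 1:n, ref = sample(c("A", "C", "G", "T"), n, TRUE),
      depth = as.integer(depth), A = counts[, 1], C = counts[, 2],
      G = counts[, 3], T = counts[, 4], DEL = 0L)
    mvf <- sample(c(0.1, 0.2, 0.3), 1)
    got <- call_snps(pile_i, mvf, 10)
    want <- oracle_call_snps(pile_i, mvf, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$pos, want$pos)
      expect_equal(as.character(got$alt), as.character(want$alt))
      expect_equal(got$frequency, want$frequency)
    }
  }
})

test_that("pool comparison classifies private, shared and fixed sites", {
  mkpile <- function(minor_at = integer(0), minor_base = "T",
                     minor_n = 50L, depth = 200L, L = 10L) {
    cols <- list(A = rep(depth, L), C = integer(L), G = integer(L),
                 T = integer(L))
    for (i in minor_at) {
      cols[[minor_base]][i] <- minor_n
      cols$A[i] <- depth - minor_n
    }
    data.table::data.table(pos = 1:L, ref = "A", depth = depth,
                           A = cols$A, C = cols$C, G = cols$G, T = cols$T,
                           DEL = 0L)
  }
  p1 <- mkpile(minor_at = 5)             # 25% T at pos 5
  p2 <- mkpile()
  c1 <- call_snps(p1, 0.2, 10, "p1"); c2 <- call_snps(p2, 0.2, 10, "p2")
  cmp <- compare_pools(list(p1 = c1, p2 = c2), list(p1 = p1, p2 = p2))
  expect_equal(cmp$variants$status, "private")
  expect_equal(nrow(cmp$fixed_differences), 0)

  ## a site where the pools are fixed for different alleles
  p3 <- mkpile(minor_at = 7, minor_base = "C", minor_n = 200L)
  cmp2 <- compare_pools(list(p1 = call_snps(p1, 0.2, 10, "p1"),
                             p3 = call_snps(p3, 0.2, 10, "p3")),
                        list(p1 = p1, p3 = p3))
  expect_equal(cmp2$fixed_differences$pos, 7L)

  ## identical pools: nothing private, nothing fixed
  cmp3 <- compare_pools(list(a = c1, b = c1), list(a = p1, b = p1))
  expect_true(all(cmp3$variants$status == "shared"))
  expect_equal(nrow(cmp3$fixed_differences), 0)
})

test_that("VCF and SAM exports are well-formed", {
  calls <- data.table::data.table(pool_id = "p1", pos = c(10L, 20L),
                                  ref = c("A", "G"), alt = c("T", "C"),
                                  frequency = c(0.25, 0.5),
                                  depth = c(200L, 180L))
  vf <- tempfile(fileext = ".vcf")
  write_vcf(list(p1 = calls), "cons", 1000L, vf)
  lines <- readLines(vf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  f <- strsplit(body[1], "\t")[[1]]
  expect_identical(f[c(1, 2, 4, 5)], c("cons", "10", "A", "T"))

  al <- data.table::data.table(read_id = "r1", pos = 5L, strand = "-",
                               seq = "ACGT", qual = "IIII", aln_len = 4L,
                               matches = 3L, n_best = 1L)
  sf <- tempfile(fileext = ".sam")
  write_sam(al, "cons", 1000L, sf)
  sl <- readLines(sf)
  expect_true(any(startsWith(sl, "@SQ")))
  f2 <- strsplit(sl[length(sl)], "\t")[[1]]
  expect_identical(f2[2], "16")
  expect_identical(f2[6], "4M")
  expect_identical(f2[length(f2)], "NM:i:1")
})
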