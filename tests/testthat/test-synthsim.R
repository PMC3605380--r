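test_that("quadripartite genomes have the constructed structure", {
  g <- make_genome(1000, 200, 300, seed = 1)
  expect_equal(genome_length(g), 1800)
  s <- genome_sequence(g)
  expect_identical(substr(s, 1501, 1800), revcomp(substr(s, 1001, 1300)))

  big <- make_genome(87022, 18352, 27070, seed = 7)
  expect_equal(genome_length(big), 159514)

  expect_identical(genome_sequence(make_genome(500, 100, 50, seed = 3)),
                   genome_sequence(make_genome(500, 100, 50, seed = 3)))
  expect_error(make_genome(0, 100, 50, seed = 1), "positive")

  reg <- genome_regions(g)
  expect_equal(reg$start, c(1L, 1001L, 1301L, 1501L))
  expect_equal(reg$end, c(1000L, 1300L, 1500L, 1800L))
})

test_that("diverge perturbs at the requested rate and keeps the invariants", {
  g <- make_genome(6000, 2000, 1000, seed = 2)  # 10 kb total
  expect_identical(genome_sequence(diverge(g, 0, 0, seed = 5)),
                   genome_sequence(g))

  d <- diverge(g, 0.1, 0, seed = 6)   # substitutions only: alignable per site
  for (r in c("lsc", "ssc", "ir")) {
    a <- strsplit(g[[r]], "")[[1]]
    b <- strsplit(d[[r]], "")[[1]]
    n <- length(a)
    frac <- mean(a != b)
    sd3 <- 3 * sqrt(0.1 * 0.9 / n)
    expect_lt(abs(frac - 0.1), sd3 + 1e-9)
  }
  di <- diverge(g, 0.1, 0.005, seed = 8)
  s <- genome_sequence(di)
  li <- nchar(di$lsc); ii <- nchar(di$ir); si <- nchar(di$ssc)
  expect_identical(substr(s, li + ii + si + 1, nchar(s)),
                   revcomp(substr(s, li + 1, li + ii)))
  expect_error(diverge(g, 0.6, 0, seed = 1), "rates")
})

test_that("pools carry planted variants at exactly |carriers|/n", {
  g <- make_genome(800, 200, 150, seed = 4)
  s <- genome_sequence(g)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  sites <- list(list(pos = 50, alt = alt_of(50), carriers = 1),
                list(pos = 300, alt = alt_of(300), carriers = integer(0)),
                list(pos = 700, alt = alt_of(700), carriers = 1:4))
  pool <- make_pool(g, 4, sites)
  fr <- pool_allele_fractions(pool)
  expect_equal(fr$frequency[fr$pos == 50], 0.25)
  expect_false(300 %in% fr$pos)  # no carriers: absent from all edits
  expect_equal(fr$frequency[fr$pos == 700], 1.0)

  ## conservation property over random carrier sets
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    carriers <- sort(sample.int(n, sample.int(n, 1)))
    p <- sample(100:1000, 1)
    pool_i <- make_pool(g, n, list(list(pos = p, alt = alt_of(p),
                                        carriers = carriers)))
    hap_alt <- sum(vapply(pool_i, function(h)
      substr(haplotype_sequence(h), p, p) != substr(s, p, p), TRUE))
    expect_equal(hap_alt, length(carriers))
  }
  expect_error(make_pool(g, 4, list(list(pos = 50, alt = alt_of(50),
                                         carriers = 5))), "carrier")
})

test_that("simulated reads are faithful, circular and deterministic", {
  g <- make_genome(1200, 300, 250, seed = 10)
  pool <- make_pool(g, 1, list())
  cfg <- sim_config(n_pairs = 300, cp_fraction = 1, per_base_error = 0,
                    seed = 11, insert_mean = 300, insert_sd = 30)
  rp <- simulate_reads(pool, cfg)
  circ <- paste0(genome_sequence(g), substr(genome_sequence(g), 1, 600))
  ok <- vapply(c(rp$r1, rp$r2), function(r)
    grepl(r, circ, fixed = TRUE) || grepl(revcomp(r), circ, fixed = TRUE),
    TRUE)
  expect_true(all(ok))

  ## byte-identical FASTQ under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq_pairs(simulate_reads(pool, cfg), f1)
  write_fastq_pairs(simulate_reads(pool, cfg), f2)
  expect_identical(readBin(paste0(f1, "_1.fastq"), "raw", 1e6),
                   readBin(paste0(f2, "_1.fastq"), "raw", 1e6))
  expect_identical(readBin(paste0(f1, "_2.fastq"), "raw", 1e6),
                   readBin(paste0(f2, "_2.fastq"), "raw", 1e6))

  ## generated coverage matches the Lander-Waterman expectation
  g2 <- make_genome(14000, 3000, 1500, seed = 12)  # 20 kb
  rp2 <- simulate_reads(make_pool(g2, 1, list()),
                        sim_config(n_pairs = 5000, cp_fraction = 1,
                                   per_base_error = 0, seed = 13))
  expect_equal(sum(nchar(c(rp2$r1, rp2$r2))) / genome_length(g2), 50,
               tolerance = 0.01)

  ## decoy background appears at 1 - cp_fraction
  rp3 <- simulate_reads(pool, sim_config(n_pairs = 400, cp_fraction = 0.05,
                                         seed = 14))
  expect_equal(sum(rp3$truth$source == "chloroplast"), 20)
  expect_error(simulate_reads(list(), cfg), "non-empty")
})
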