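test_that("trivial inputs assemble to themselves", {
  set.seed(1)
  read <- rand_dna(300)
  ctg <- assemble(read, 31, min_contig_len = 0)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(read, revcomp(read)))
  ## below the contig length floor
  short <- rand_dna(150)
  expect_equal(nrow(assemble(short, 31, min_contig_len = 200)), 0)
  expect_error(assemble(read, 30), "odd")
  expect_error(assemble("ACGT", 31), "read length")
})

test_that("deep error-free reads from a repeat-free sequence give one exact contig", {
  set.seed(2)
  src <- rand_dna(5000)
  reads <- reads_from_linear(src, 100, 4)  # 50x, both strands
  ctg <- assemble(reads, 31)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(src, revcomp(src)))

  ## no chimeric k-mers: every contig k-mer occurs in some read
  read_kmers <- unique(plastidkit:::seq_kmers(c(reads, revcomp(reads)), 31))
  contig_kmers <- unique(plastidkit:::seq_kmers(ctg$sequence, 31))
  expect_true(all(contig_kmers %in% read_kmers))
})

test_that("the inverted repeat collapses to a single contig", {
  g <- make_genome(3000, 800, 900, seed = 30)
  rp <- simulate_reads(make_pool(g, 1, list()),
                       sim_config(n_pairs = 1500, cp_fraction = 1,
                                  per_base_error = 0, seed = 31))
  ctg <- assemble(rp, 31)
  expect_equal(nrow(ctg), 3)  # LSC, SSC and one collapsed IR unitig
  ir_core <- substr(g$ir, 5, nchar(g$ir) - 4)
  holds_ir <- vapply(ctg$sequence, function(s)
    grepl(ir_core, s, fixed = TRUE) || grepl(ir_core, revcomp(s),
                                             fixed = TRUE), TRUE)
  expect_equal(sum(holds_ir), 1)
})

test_that("n50 matches the cumulative-sum oracle", {
  expect_equal(n50(c(300, 200, 100)), 300)
  expect_equal(n50(100), 100)
  expect_equal(n50(c(50, 50, 50, 50)), 50)
  expect_error(n50(numeric(0)), "non-empty")
  set.seed(3)
  for (i in 1:20) {
    lens <- sample(50:5000, sample(1:30, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("k sweep selects by N50 with the documented tie-breaks", {
  set.seed(4)
  read <- rand_dna(300)
  sw1 <- k_sweep(read, 31, min_contig_len = 0)
  expect_equal(sw1$chosen_k, 31)
  ## identical stats at every k: smallest k wins
  sw2 <- k_sweep(read, c(35, 31, 33), min_contig_len = 0)
  expect_true(all(sw2$stats$n50 == sw2$stats$n50[1]))
  expect_equal(sw2$chosen_k, 31)

  src <- rand_dna(4000)
  reads <- reads_from_linear(src, 100, 4)
  sw3 <- k_sweep(reads, c(31, 41, 51))
  expect_equal(sw3$stats$n50[sw3$stats$k == sw3$chosen_k], 4000)
})

test_that("contig FASTA round-trips through the drop-in reader", {
  set.seed(5)
  src <- rand_dna(1000)
  ctg <- assemble(reads_from_linear(src, 100, 5), 31)
  f <- tempfile(fileext = ".fasta")
  write_contigs(ctg, f)
  back <- read_contigs(f, k = 31)
  expect_identical(back$sequence, ctg$sequence)
  expect_identical(back$id, ctg$id)
})
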