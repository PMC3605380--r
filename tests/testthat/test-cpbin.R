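test_that("Karlin-Altschul parameters satisfy their defining identities", {
  ka <- karlin_altschul(1, -2)
  ## lambda is the root of 0.25 e^lambda + 0.75 e^(-2 lambda) = 1
  expect_equal(0.25 * exp(ka$lambda) + 0.75 * exp(-2 * ka$lambda), 1,
               tolerance = 1e-9)
  ## +1/-1 has the classical closed form K = (q - p)^2 / q with p=1/4, q=3/4
  ka11 <- karlin_altschul(1, -1)
  expect_equal(ka11$lambda, log(3), tolerance = 1e-9)
  expect_equal(ka11$K, (0.75 - 0.25)^2 / 0.75, tolerance = 1e-3)
  expect_error(karlin_altschul(-1, -2), "match")
})

test_that("seed_extend finds exact and reverse-complement matches", {
  set.seed(10)
  db <- rand_dna(5000)
  ctg <- substr(db, 1001, 1500)
  h <- seed_extend(ctg, db)
  expect_equal(h$score[1], 500)
  expect_lt(h$evalue[1], 1e-180)
  expect_equal(c(h$db_start[1], h$db_end[1]), c(1001, 1500))
  hrc <- seed_extend(revcomp(ctg), db)
  expect_equal(hrc$score[1], 500)
  expect_equal(hrc$strand[1], "-")
  expect_error(seed_extend("", db), "empty")
})

test_that("a random short query finds nothing significant in a large genome", {
  set.seed(11)
  q50 <- rand_dna(50)
  big <- rand_dna(150000)
  h <- seed_extend(q50, big)
  if (nrow(h)) expect_gt(min(h$evalue), 1e-3)
})

test_that("seed_extend scores equal the brute-force local-alignment oracle", {
  set.seed(12)
  for (i in 1:8) {
    db <- rand_dna(200)
    ## plant a homologous segment with mismatches spaced beyond the seed word
    seg_len <- sample(60:120, 1)
    start <- sample(1:(200 - seg_len), 1)
    seg <- substr(db, start, start + seg_len - 1)
    ch <- strsplit(seg, "")[[1]]
    for (p in seq(15, seg_len - 5, by = 25))
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    contig <- paste0(rand_dna(20), paste(ch, collapse = ""), rand_dna(20))
    got <- max(seed_extend(contig, db)$score)
    expect_equal(got, oracle_local_score(contig, db))
  }
})

test_that("lengthening an exact match never increases its E-value", {
  ka <- karlin_altschul(1, -2)
  ev <- vapply(seq(20, 400, by = 20), function(l)
    evalue(l, l, 150000, ka), 0)
  expect_true(all(diff(ev) <= 0))
})

test_that("binning separates chloroplast from decoy contigs", {
  g <- make_genome(4000, 1000, 800, seed = 40)
  rel <- diverge(g, 0.10, 0.005, seed = 41)       # database relative
  s <- genome_sequence(g)
  set.seed(42)
  cp_pieces <- vapply(c(1, 2000, 4500), function(p)
    substr(s, p, p + 799), "")
  decoys <- vapply(1:3, function(i) rand_dna(800), "")
  contigs <- data.table::data.table(
    id = sprintf("c%d", 1:6), sequence = c(cp_pieces, decoys),
    length = 800L, k = 31L, mean_kmer_coverage = 10)
  class(contigs) <- c("contig_set", class(contigs))
  res <- bin_contigs(contigs, stats::setNames(genome_sequence(rel), "rel"))
  expect_setequal(res$kept$id, c("c1", "c2", "c3"))

  ## spelled-out threshold behaviour
  expect_true(all(res$hits[res$hits$contig_id %in% c("c1", "c2", "c3"),
                           ]$evalue <= 1e-180))
  empty <- bin_contigs(contigs[0, ], stats::setNames("ACGTACGT", "x"))
  expect_equal(nrow(empty$kept), 0)
})
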