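test_that("split_reference follows the two-half interval arithmetic", {
  g <- make_genome(1000, 200, 300, seed = 1)  # IRb 1001..1300, total 1800
  sp <- split_reference(g, ssc_overhang = 100, overlap = 150)
  expect_equal(c(sp$ref_a$start, sp$ref_a$end), c(1, 1400))
  expect_equal(nchar(sp$ref_a$sequence), 1400)
  expect_equal(c(sp$ref_b$start, sp$ref_b$end), c(1151, 1800))
  expect_equal(nchar(sp$ref_b$sequence), 650)
  expect_equal(sp$overlap_len, 250)
  expect_error(split_reference(g, 100, 0), "overlap")
  expect_error(split_reference(g, 100, 300), "overlap")
  ## a plain sequence without an IR is a structural error
  set.seed(2)
  expect_error(split_reference(rand_dna(5000), 100, 150, min_ir_len = 500),
               "inverted repeat")
})

test_that("detect_ir agrees with the exhaustive oracle on small fixtures", {
  for (sd in 1:6) {
    g <- make_genome(700, 150, 250, seed = sd)   # 1350 bp
    s <- genome_sequence(g)
    o <- oracle_ir(s, 100)
    ann <- detect_ir(s, min_ir_len = 100)
    irb <- ann$regions[ann$regions$region == "IRb", ]
    ira <- ann$regions[ann$regions$region == "IRa", ]
    expect_equal(c(irb$start, irb$end, ira$start, ira$end), o)
    ## the two annotated copies really are reverse complements
    expect_identical(substr(s, ira$start, ira$end),
                     revcomp(substr(s, irb$start, irb$end)))
  }
  set.seed(9)
  expect_equal(nrow(detect_ir(rand_dna(500), min_ir_len = 100)$regions), 0)
})

test_that("region lengths of a full-size plastome are annotated exactly", {
  g <- make_genome(87022, 18352, 27070, seed = 5)
  ann <- detect_ir(genome_sequence(g), min_ir_len = 1000)
  lens <- setNames(ann$regions$end - ann$regions$start + 1,
                   ann$regions$region)
  expect_equal(unname(lens[c("LSC", "IRb", "SSC", "IRa")]),
               c(87022, 27070, 18352, 27070))
  expect_equal(ann$junctions$junction,
               c("J(LSC,IRb)", "J(IRb,SSC)", "J(SSC,IRa)", "J(IRa,LSC)"))
  expect_equal(ann$junctions$left[4], 159514)
  expect_equal(ann$junctions$right[4], 1)
})

test_that("contigs place with the right strand, identity and IR duplication", {
  g <- make_genome(3000, 800, 900, seed = 50)
  s <- genome_sequence(g)
  sp <- split_reference(g, ssc_overhang = 300, overlap = 400)
  contigs <- data.table::data.table(
    id = c("exact", "ir", "junk"),
    sequence = c(substr(sp$ref_a$sequence, 500, 1100),  # LSC interior
                 substr(s, 3101, 3800),                 # wholly inside IRb
                 {set.seed(51); rand_dna(600)}),
    length = c(601L, 700L, 600L), k = 31L, mean_kmer_coverage = 10)
  class(contigs) <- c("contig_set", class(contigs))
  pl <- place_contigs(contigs, sp)
  ex <- pl[pl$contig_id == "exact", ]
  expect_equal(nrow(ex), 1)
  expect_equal(ex$strand, "+")
  expect_equal(ex$identity, 1.0)
  expect_equal(c(ex$ref_start, ex$ref_end), c(500, 1100))
  iru <- pl[pl$contig_id == "ir", ]
  expect_setequal(iru$scaffold, c("A", "B"))  # both IR copies
  expect_true(all(iru$in_ir))
  expect_false("junk" %in% pl$contig_id)
})

test_that("vote majority and stitching follow the documented column rules", {
  expect_equal(vote_majority(c("A", "A", "T"))$base, "A")
  tie <- vote_majority(c("A", "T"))
  expect_equal(tie$base, "A")          # lexicographically smallest
  expect_true(tie$ambiguous)

  ## overlapping contigs merge; disjoint contigs concatenate with a gap flag
  set.seed(52)
  src <- rand_dna(900)
  st <- plastidkit:::stitch_sequences(list(substr(src, 1, 500),
                                           substr(src, 451, 900)))
  expect_identical(st$sequence, src)
  expect_length(st$gap_flags, 0)

  far <- plastidkit:::stitch_sequences(list(substr(src, 1, 300),
                                            substr(src, 601, 900)))
  expect_identical(far$sequence, paste0(substr(src, 1, 300),
                                        substr(src, 601, 900)))
  expect_equal(far$gap_flags, 300)
})

test_that("vote-majority consensus is invariant under contig order", {
  set.seed(53)
  src <- rand_dna(1200)
  pieces <- list(substr(src, 1, 400), substr(src, 351, 800),
                 substr(src, 741, 1200), substr(src, 101, 900))
  ords <- list(1:4, c(4, 1, 3, 2), c(2, 3, 1, 4))
  refs <- vapply(ords, function(o) {
    ## keep reference order semantics: sort pieces by their true start
    sorted <- pieces[o][order(c(1, 351, 741, 101)[o])]
    plastidkit:::stitch_sequences(sorted)$sequence
  }, "")
  expect_true(all(refs == src))
})

test_that("the scaffolder rebuilds a genome exactly from its own contigs", {
  fx <- tiny_fixture(seed = 61, n_pairs = 700)  # ~22x on 6.4 kb
  contigs <- data.table::rbindlist(list(assemble(fx$reads, 31),
                                        assemble(fx$reads, 41)))
  class(contigs) <- c("contig_set", class(contigs))
  res <- bin_contigs(contigs,
                     stats::setNames(genome_sequence(fx$reference), "rel"))
  sp <- split_reference(fx$reference, ssc_overhang = 300, overlap = 400)
  pl <- place_contigs(res$kept, sp)
  cons <- consensus_and_merge(pl, res$kept, sp, min_ir_len = 500)
  expect_identical(cons$sequence, fx$truth)
  expect_equal(nrow(cons$junctions), 4)
  expect_equal(cons$ir_mismatches, 0)
})

test_that("region annotation exports as GFF3 and BED", {
  g <- make_genome(3000, 800, 900, seed = 70)
  ann <- detect_ir(genome_sequence(g), min_ir_len = 500)
  cons <- structure(list(sequence = genome_sequence(g),
                         regions = ann$regions, junctions = ann$junctions,
                         gap_flags = integer(0), ambiguous_sites = integer(0),
                         ir_mismatches = 0L),
                    class = "consensus_genome")
  gff <- tempfile(fileext = ".gff3"); bed <- tempfile(fileext = ".bed")
  write_region_annotation(cons, gff, bed)
  back <- rtracklayer::import(gff)
  expect_setequal(as.character(back$ID), c("LSC", "IRb", "SSC", "IRa"))
  bedback <- rtracklayer::import(bed)
  expect_equal(length(bedback), 4)
})
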