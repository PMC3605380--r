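gt_table <- function(haps, pops) {
  loci <- nchar(haps[1])
  m <- do.call(rbind, strsplit(haps, ""))
  colnames(m) <- sprintf("locus%d", seq_len(loci))
  cbind(data.frame(individual = sprintf("i%02d", seq_along(haps)),
                   population = pops, stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE))
}

test_that("chlorotypes group identical haplotype strings in input order", {
  gt <- gt_table(c("AAAAAAA", "AAAAAAA", "AAAAAAT", "AAAATAT"),
                 rep("p1", 4))
  ct <- build_chlorotypes(gt)
  expect_length(ct, 3)
  expect_equal(vapply(ct, function(x) length(x$members), 0L), c(2L, 1L, 1L))
  expect_equal(ct[[1]]$haplotype, "AAAAAAA")

  ct1 <- build_chlorotypes(gt_table(rep("ACGT", 5), rep("p1", 5)))
  expect_length(ct1, 1)

  ## individuals with missing alleles are dropped with a warning
  gt$locus3[2] <- NA
  expect_warning(ct2 <- build_chlorotypes(gt), "missing")
  expect_equal(sum(vapply(ct2, function(x) length(x$members), 0L)), 3)

  ## homopolymer-locus blacklist is applied before grouping
  ct3 <- build_chlorotypes(gt_table(c("AT", "AA"), c("p1", "p2")),
                           blacklist = "locus2")
  expect_length(ct3, 1)
})

test_that("a planted six-type table yields six chlorotypes", {
  gt <- simulate_genotypes(n_chlorotypes = 6, n_loci = 7,
                           populations = paste0("pop", 1:5),
                           n_individuals = 32, seed = 3)
  ct <- build_chlorotypes(gt)
  expect_length(ct, 6)
  expect_setequal(vapply(ct, `[[`, "", "haplotype"), attr(gt, "planted"))
})

test_that("median-joining reproduces the classical small topologies", {
  ## two types one step apart: a single edge, no medians
  n2 <- mj_network(c("AA", "AT"))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$weight, 1)
  expect_false(any(n2$nodes$type == "median"))

  ## the {110, 101, 011} triplet gains the 111 quasi-median star
  n3 <- mj_network(c("TTA", "TAT", "ATT"))
  med <- n3$nodes[n3$nodes$type == "median", ]
  expect_equal(med$haplotype, "TTT")
  expect_equal(nrow(n3$edges), 3)
  expect_true(all(n3$edges$weight == 1))
  expect_true(all(med$id %in% c(n3$edges$from, n3$edges$to)))

  ## a mutation chain stays a path with no medians
  nc <- mj_network(c("AAA", "AAT", "ATT"))
  expect_false(any(nc$nodes$type == "median"))
  expect_equal(sort(nc$edges$weight), c(1, 1))
  expect_error(mj_network(c("AA", "AT"), epsilon = -1), "epsilon")
})

test_that("on tree-like data the network equals the minimum spanning tree", {
  ## sequential unique mutations: distances are tree additive
  haps <- c("AAAAAAAA")
  for (i in 1:5) {
    h <- strsplit(tail(haps, 1), "")[[1]]
    h[i] <- "T"
    haps <- c(haps, paste(h, collapse = ""))
  }
  net <- mj_network(haps)
  expect_false(any(net$nodes$type == "median"))
  expect_equal(nrow(net$edges), length(haps) - 1)   # a tree
  expect_true(all(net$edges$weight == 1))
  expect_true(igraph::is_connected(net$graph))
})

test_that("network structure is invariant under input permutation", {
  haps <- c("AAAA", "AAAT", "AATT", "TTAA", "ATAA")
  canon <- function(net) {
    e <- net$edges
    key <- apply(cbind(net$nodes$haplotype[e$from],
                       net$nodes$haplotype[e$to]), 1,
                 function(x) paste(sort(x), collapse = "|"))
    sort(paste(key, e$weight))
  }
  n1 <- mj_network(haps)
  n2 <- mj_network(rev(haps))
  expect_setequal(n1$nodes$haplotype, n2$nodes$haplotype)
  expect_identical(canon(n1), canon(n2))
})

test_that("path weights dominate Hamming distances", {
  haps <- c("AAAA", "AATT", "TTAA", "ATAT")
  net <- mj_network(haps)
  g <- net$graph
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  obs <- which(net$nodes$type == "observed")
  for (i in obs) for (j in obs) {
    if (i >= j) next
    hd <- plastidkit:::hamming(net$nodes$haplotype[i],
                               net$nodes$haplotype[j])
    expect_gte(d[i, j] + 1e-9, hd)
  }
})

test_that("population summaries count and share chlorotypes correctly", {
  gt <- gt_table(c("AA", "AA", "AT", "AA", "TT"),
                 c("p1", "p1", "p1", "p2", "p3"))
  ct <- build_chlorotypes(gt)
  ps <- population_summary(ct)
  expect_equal(ps$per_population$n_chlorotypes[
    ps$per_population$population == "p1"], 2)
  expect_equal(ps$shared$haplotype, "AA")
  expect_equal(ps$shared$n_populations, 2)

  one <- population_summary(build_chlorotypes(gt_table("AA", "p1")))
  expect_equal(nrow(one$per_population), 1)
  expect_equal(nrow(one$shared), 0)
  empty <- population_summary(list())
  expect_equal(nrow(empty$per_population), 0)
})

test_that("network export writes GML and an edge list", {
  net <- mj_network(c("TTA", "TAT", "ATT"))
  gml <- tempfile(fileext = ".gml"); ed <- tempfile(fileext = ".tsv")
  write_network(net, gml, ed)
  g2 <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::gorder(g2), 4)
  tab <- read.table(ed, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
})
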