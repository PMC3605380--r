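## haplonet: chlorotypes (chloroplast haplotypes over scored SNP loci) and
## Bandelt-style median-joining networks with per-population summaries.

#' Build chlorotypes from a genotype table
#'
#' Concatenates each individual's alleles over the scored SNP loci (in fixed
#' column order) and groups identical haplotype strings into chlorotypes,
#' ordered by first occurrence. Individuals with any missing allele (`NA` or
#' `"N"`/`""`) are dropped with a warning. Loci named in `blacklist` (e.g.
#' SNPs in homopolymer repeat regions) are excluded before grouping.
#'
#' @param genotypes data.frame with columns `individual`, `population`, and
#'   one column per SNP locus.
#' @param blacklist character vector of locus column names to exclude.
#' @return list of `chlorotype` entries: `haplotype`, `members`,
#'   `population_counts`; the list carries the locus names as
#'   `attr(, "loci")`.
#' @export
build_chlorotypes <- function(genotypes, blacklist = character(0)) {
  stopifnot(all(c("individual", "population") %in% names(genotypes)))
  loci <- setdiff(names(genotypes), c("individual", "population"))
  loci <- setdiff(loci, blacklist)
  if (!length(loci)) stop("no loci left after blacklisting", call. = FALSE)
  alle <- as.matrix(genotypes[, loci, drop = FALSE])
  missing <- apply(alle, 1L, function(x) any(is.na(x) | x %in% c("", "N")))
  if (any(missing)) {
    warning(sprintf("dropping %d individual(s) with missing alleles",
                    sum(missing)))
    genotypes <- genotypes[!missing, , drop = FALSE]
    alle <- alle[!missing, , drop = FALSE]
  }
  haps <- apply(alle, 1L, paste, collapse = "")
  out <- lapply(unique(haps), function(h) {
    sel <- haps == h
    structure(list(
      haplotype = h,
      members = genotypes$individual[sel],
      population_counts = table(as.character(genotypes$population[sel]))),
      class = "chlorotype")
  })
  attr(out, "loci") <- loci
  out
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

hamming_matrix <- function(haps) {
  n <- length(haps)
  m <- matrix(0L, n, n)
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- hamming(haps[i], haps[j])
  m
}

## minimum-spanning-network edges: (u, v) is kept when d(u, v) is within
## epsilon of the bottleneck (minimax) distance between u and v
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(data.table(from = integer(0), to = integer(0),
                                weight = integer(0)))
  gfull <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE)
  mst <- igraph::mst(gfull, algorithm = "prim")
  edges <- list()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    path <- igraph::shortest_paths(mst, i, j, output = "epath")$epath[[1]]
    bottleneck <- max(igraph::E(mst)$weight[as.integer(path)])
    if (d[i, j] <= bottleneck + epsilon)
      edges[[length(edges) + 1L]] <- data.table(from = i, to = j,
                                                weight = d[i, j])
  }
  rbindlist(edges)
}

mst_total <- function(d) {
  if (nrow(d) < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

## quasi-median(s) of three haplotype strings: per-locus majority; loci with
## three distinct alleles spawn all variants
quasi_medians <- function(a, b, c) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  cc <- strsplit(c, "")[[1]]
  opts <- lapply(seq_along(ca), function(i) {
    x <- c(ca[i], cb[i], cc[i])
    tab <- table(x)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else unique(x)
  })
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  sort(unique(apply(grid, 1L, paste, collapse = "")))
}

#' Median-joining network of chlorotypes
#'
#' Bandelt-style construction: links within `epsilon` of the
#' minimum-spanning threshold are retained; for each connected triplet the
#' quasi-median (per-locus majority, ties spawning all variants) is added
#' as an inferred node when it shortens the network; the procedure iterates
#' to a fixpoint and median vectors that no longer shorten the network are
#' pruned.
#'
#' @param chlorotypes list from [build_chlorotypes()] (or a character vector
#'   of haplotype strings).
#' @param epsilon relaxation parameter (`>= 0`); 0 gives the strict
#'   minimum-spanning network plus medians.
#' @param max_iter safety cap on median-adding rounds.
#' @return a `haplo_network`: list with `nodes` (data.frame: `id`,
#'   `haplotype`, `type` observed/median, `size`), `edges` (data.frame:
#'   `from`, `to`, `weight`), `epsilon`, and the `igraph` object as `graph`.
#' @export
mj_network <- function(chlorotypes, epsilon = 0L, max_iter = 10L) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (is.character(chlorotypes)) {
    haps <- chlorotypes
    sizes <- rep(1L, length(haps))
  } else {
    haps <- vapply(chlorotypes, `[[`, "", "haplotype")
    sizes <- vapply(chlorotypes, function(x) length(x$members), 0L)
  }
  if (!length(haps)) stop("at least one chlorotype required", call. = FALSE)
  stopifnot(!anyDuplicated(haps))
  observed <- haps
  nodes <- haps

  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix(nodes)
    ed <- msn_edges(d, epsilon)
    if (!nrow(ed)) break
    base_len <- mst_total(d)
    ## connected triplets: pairs of edges sharing a node
    adj <- lapply(seq_along(nodes), function(i)
      sort(unique(c(ed$to[ed$from == i], ed$from[ed$to == i]))))
    cand <- character(0)
    for (v in seq_along(nodes)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
        cand <- c(cand, quasi_medians(nodes[v], nodes[nb[a]], nodes[nb[b]]))
      }
    }
    cand <- sort(setdiff(unique(cand), nodes))
    added <- FALSE
    for (q in cand) {
      d2 <- hamming_matrix(c(nodes, q))
      if (mst_total(d2) < base_len) {
        nodes <- c(nodes, q)
        added <- TRUE
        break  # re-derive links before the next median
      }
    }
    if (!added) break
  }

  ## prune median vectors whose removal does not lengthen the network
  repeat {
    med <- setdiff(nodes, observed)
    if (!length(med)) break
    total <- mst_total(hamming_matrix(nodes))
    droppable <- NULL
    for (q in med) {
      rest <- setdiff(nodes, q)
      if (mst_total(hamming_matrix(rest)) <= total) { droppable <- q; break }
    }
    if (is.null(droppable)) break
    nodes <- setdiff(nodes, droppable)
  }

  d <- hamming_matrix(nodes)
  ed <- msn_edges(d, epsilon)
  node_df <- data.frame(
    id = seq_along(nodes), haplotype = nodes,
    type = ifelse(nodes %in% observed, "observed", "median"),
    size = ifelse(nodes %in% observed, sizes[match(nodes, observed)], 0L))
  g <- igraph::graph_from_data_frame(
    as.data.frame(ed[, .(from, to, weight)]), directed = FALSE,
    vertices = node_df)
  structure(list(nodes = node_df, edges = as.data.frame(ed),
                 epsilon = epsilon, graph = g),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d observed + %d median nodes, %d edges (epsilon %d)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Per-population chlorotype summary
#'
#' Counts distinct chlorotypes per population and lists chlorotypes shared
#' across more than one population.
#'
#' @param chlorotypes list from [build_chlorotypes()].
#' @return list with `per_population` (population, n_individuals,
#'   n_chlorotypes) and `shared` (haplotype, n_populations, populations).
#' @export
population_summary <- function(chlorotypes) {
  if (!length(chlorotypes))
    return(list(per_population = data.frame(population = character(0),
                                            n_individuals = integer(0),
                                            n_chlorotypes = integer(0)),
                shared = data.frame(haplotype = character(0),
                                    n_populations = integer(0),
                                    populations = character(0))))
  rows <- rbindlist(lapply(seq_along(chlorotypes), function(i) {
    ct <- chlorotypes[[i]]
    data.table(chlorotype = i, haplotype = ct$haplotype,
               population = names(ct$population_counts),
               count = as.integer(ct$population_counts))
  }))
  per_pop <- rows[, .(n_individuals = sum(count), n_chlorotypes = .N),
                  by = population]
  shared <- rows[, .(n_populations = .N,
                     populations = paste(sort(population), collapse = ",")),
                 by = haplotype][n_populations > 1L]
  list(per_population = as.data.frame(per_pop),
       shared = as.data.frame(shared))
}

#' Write a haplotype network as GML and/or an edge-list TSV
#'
#' @param net a `haplo_network`.
#' @param gml_path,edges_path output paths (`NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_network <- function(net, gml_path = NULL, edges_path = NULL) {
  paths <- character(0)
  if (!is.null(gml_path)) {
    igraph::write_graph(net$graph, gml_path, format = "gml")
    paths <- c(paths, gml_path)
  }
  if (!is.null(edges_path)) {
    ed <- net$edges
    ed$from_haplotype <- net$nodes$haplotype[ed$from]
    ed$to_haplotype <- net$nodes$haplotype[ed$to]
    write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, edges_path)
  }
  invisible(paths)
}

#' Simulate a genotype table with a planted chlorotype structure
#'
#' Generates `n_individuals` across populations with a fixed set of distinct
#' haplotype strings over `n_loci` biallelic SNP loci, for exercising
#' [build_chlorotypes()], [mj_network()] and [population_summary()] without
#' real genotypes.
#'
#' @param n_chlorotypes distinct haplotype strings to plant.
#' @param n_loci number of SNP loci.
#' @param populations character vector of population names.
#' @param n_individuals total individuals.
#' @param seed integer seed.
#' @return data.frame in the [build_chlorotypes()] input format; the planted
#'   strings are attached as `attr(, "planted")`.
#' @export
simulate_genotypes <- function(n_chlorotypes = 6L, n_loci = 7L,
                               populations = paste0("pop", 1:5),
                               n_individuals = 32L, seed = 1L) {
  stopifnot(n_chlorotypes >= 1L, n_individuals >= n_chlorotypes)
  with_seed(seed, {
    ref <- sample(DNA_BASES, n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    haps <- character(0)
    while (length(haps) < n_chlorotypes) {
      pick <- runif(n_loci) < 0.35
      h <- paste(ifelse(pick, alt, ref), collapse = "")
      haps <- unique(c(haps, h))
    }
    assign_hap <- c(seq_len(n_chlorotypes),
                    sample.int(n_chlorotypes, n_individuals - n_chlorotypes,
                               replace = TRUE))
    pops <- sort(rep_len(populations, n_individuals))
    out <- data.frame(individual = sprintf("ind%02d", seq_len(n_individuals)),
                      population = pops, stringsAsFactors = FALSE)
    allemat <- do.call(rbind, strsplit(haps[assign_hap], ""))
    colnames(allemat) <- sprintf("locus%d", seq_len(n_loci))
    out <- cbind(out, as.data.frame(allemat, stringsAsFactors = FALSE))
    attr(out, "planted") <- haps
    out
  })
}
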