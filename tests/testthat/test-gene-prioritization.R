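make_net <- function(edge_rows) {
  suppressMessages(read_edge_list(write_tsv_fixture(edge_rows)))
}

test_that("direct partners are one-hop neighbors with seeds excluded", {
  net <- make_net(c("S\tA", "A\tB"))
  expect_equal(direct_partners("S", net), "A")
  net2 <- make_net("S1\tS2")
  expect_equal(direct_partners(c("S1", "S2"), net2), character(0))
  expect_equal(direct_partners("ABSENT", net), character(0))
  expect_error(direct_partners(character(0), net), "nonempty")
})

test_that("direct partners agree with an igraph one-hop oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(12)
  genes <- sprintf("G%02d", 1:15)
  rows <- replicate(30, paste(sample(genes, 2), collapse = "\t"))
  net <- make_net(rows)
  seeds <- c("G01", "G05", "G09")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  present <- intersect(seeds, igraph::V(g)$name)
  oracle <- setdiff(unique(unlist(lapply(igraph::adjacent_vertices(g, present), names))),
                    seeds)
  expect_setequal(direct_partners(seeds, net), oracle)
})

test_that("consensus partners is the exact intersection", {
  expect_equal(consensus_partners(list(c("A", "B", "C"), c("B", "C"), c("C", "D", "B"))),
               c("B", "C"))
  expect_equal(consensus_partners(list(c("A", "B"), character(0))), character(0))
  expect_error(consensus_partners(list(c("A"))), "at least 2")
  # membership oracle on random sets
  set.seed(4)
  sets <- replicate(3, sample(sprintf("G%d", 1:20), 20, replace = TRUE), simplify = FALSE)
  cons <- consensus_partners(sets)
  for (g in unique(unlist(sets))) {
    expect_equal(g %in% cons, all(vapply(sets, function(s) g %in% s, TRUE)))
  }
})

toy_map <- function(pairs) {
  read_gene_phenotype_map(write_tsv_fixture(pairs))
}

test_that("the pooled disease phenotype set is the union of seed annotations", {
  map <- toy_map(c("S1\ta", "S1\tb", "S2\tb", "S2\tc"))
  pws <- ws_phenotype_union(c("S1", "S2"), map)
  expect_equal(pws$terms, c("a", "b", "c"))
  expect_equal(pws$n, 3L)
  expect_equal(ws_phenotype_union("S1", map)$terms, c("a", "b"))
  expect_warning(ws_phenotype_union(c("S1", "S2", "SX"), map), "SX")
  expect_error(suppressWarnings(ws_phenotype_union(c("SX", "SY"), map)), "none of the seed genes")
})

test_that("union size matches brute-force counting for 7 synthetic seeds", {
  set.seed(21)
  seeds <- sprintf("S%d", 1:7)
  pairs <- unlist(lapply(seeds, function(s)
    paste(s, sample(sprintf("HP:%02d", 1:40), sample(5:15, 1)), sep = "\t")))
  map <- toy_map(pairs)
  pws <- ws_phenotype_union(seeds, map)
  raw <- do.call(rbind, strsplit(pairs, "\t"))
  expect_equal(pws$n, length(unique(raw[, 2])))
})

test_that("phenotype weight is the exact overlap ratio with strict selection at the boundary", {
  n_ws <- 70
  terms <- sprintf("HP:%02d", 1:n_ws)
  pairs <- c(paste("SEED", terms, sep = "\t"),
             paste("G15", terms[1:15], sep = "\t"),
             paste("G14", terms[1:14], sep = "\t"),
             paste("GFULL", terms, sep = "\t"))
  map <- toy_map(pairs)
  pws <- ws_phenotype_union("SEED", map)
  expect_equal(pws$n, 70L)
  expect_equal(phenotype_weight("GFULL", pws, map)$weight, 1.0)
  w15 <- phenotype_weight("G15", pws, map)
  expect_equal(w15$n_overlap, 15L)
  expect_equal(w15$weight, 15 / 70, tolerance = 1e-12)
  expect_gt(w15$weight, 0.2)
  w14 <- phenotype_weight("G14", pws, map)
  expect_equal(w14$weight, 0.2, tolerance = 1e-12)
  weights <- phenotype_weights(c("G15", "G14", "GFULL"), pws, map)
  expect_equal(select_set_B(weights, 0.2, seeds = "SEED"), c("G15", "GFULL"))
  # weight 0 for unannotated genes; threshold 0 keeps any gene with N_g >= 1
  expect_equal(phenotype_weight("NOPE", pws, map)$weight, 0)
  expect_setequal(select_set_B(weights, 0), c("G14", "G15", "GFULL"))
})

test_that("threshold selection equals a brute-force overlap-count rule on planted genes", {
  set.seed(33)
  n_ws <- 70
  terms <- sprintf("HP:%02d", 1:n_ws)
  n_g <- sample(0:25, 100, replace = TRUE)
  genes <- sprintf("P%03d", 1:100)
  pairs <- c(paste("SEED", terms, sep = "\t"),
             unlist(lapply(which(n_g > 0), function(i)
               paste(genes[i], terms[seq_len(n_g[i])], sep = "\t"))))
  map <- toy_map(pairs)
  pws <- ws_phenotype_union("SEED", map)
  weights <- phenotype_weights(genes, pws, map)
  expect_setequal(select_set_B(weights, 0.2, "SEED"),
                  genes[n_g > 0.2 * n_ws])
})

test_that("weights grow monotonically with the gene's annotation", {
  map <- toy_map(c("SEED\ta", "SEED\tb", "SEED\tc", "G\ta"))
  map2 <- toy_map(c("SEED\ta", "SEED\tb", "SEED\tc", "G\ta", "G\tb"))
  pws <- ws_phenotype_union("SEED", map)
  expect_gte(phenotype_weight("G", pws, map2)$weight,
             phenotype_weight("G", pws, map)$weight)
})

test_that("prioritize intersects sets deterministically and excludes seeds", {
  cand <- prioritize(c("SIN3A", "EP300", "CHD7", "KIT", "X"),
                     c("SIN3A", "EP300", "CHD7", "KIT", "Y"))
  expect_equal(cand$preliminary, c("CHD7", "EP300", "KIT", "SIN3A"))
  expect_equal(prioritize(c("A", "B"), c("C", "D"))$preliminary, character(0))
  with_seed <- prioritize(c("PAX3", "KIT"), c("PAX3", "KIT"), seeds = "PAX3")
  expect_equal(with_seed$preliminary, "KIT")
  set.seed(5)
  a <- sample(LETTERS, 12); b <- sample(LETTERS, 12)
  expect_setequal(prioritize(a, b)$preliminary, a[a %in% b])
})

test_that("adding an edge can only grow set A; adding a source can only shrink the consensus", {
  net1 <- make_net(c("S\tA", "S\tB"))
  net2 <- make_net(c("S\tA", "S\tB", "S\tC"))
  expect_true(all(direct_partners("S", net1) %in% direct_partners("S", net2)))
  sets <- list(c("A", "B", "C"), c("A", "B"))
  expect_true(all(consensus_partners(c(sets, list(c("A")))) %in% consensus_partners(sets)))
})

test_that("evidence filtering keeps genes with all required flags true", {
  ev <- read_evidence_table(write_tsv_fixture(c(
    "gene\thearing_impairment_in_mouse\tear_expression_support",
    "SIN3A\t0\t1", "EP300\t0\t0", "CHD7\t1\t1", "KIT\t1\t1")))
  prelim <- c("SIN3A", "EP300", "CHD7", "KIT")
  expect_equal(evidence_filter(prelim, ev, "hearing_impairment_in_mouse"),
               c("CHD7", "KIT"))
  expect_equal(evidence_filter(prelim, ev, character(0)), sort(prelim))
  expect_error(evidence_filter(prelim, ev, "nonexistent_flag"), "unknown")
  expect_message(
    expect_equal(evidence_filter(c("CHD7", "NOVEL1"), ev, "ear_expression_support"), "CHD7"),
    "NOVEL1")
  # row-wise AND oracle on random flags
  set.seed(8)
  flags <- data.frame(gene = sprintf("G%d", 1:10),
                      f1 = sample(c(TRUE, FALSE), 10, replace = TRUE),
                      f2 = sample(c(TRUE, FALSE), 10, replace = TRUE))
  got <- evidence_filter(flags$gene, flags, c("f1", "f2"))
  expect_setequal(got, flags$gene[flags$f1 & flags$f2])
})

test_that("shared phenotype counts report per-gene overlaps and the distinct total", {
  map <- toy_map(c("SEED\ta", "SEED\tb", "SEED\tc",
                   "G1\ta", "G1\tb", "G2\tb", "G3\tzz"))
  pws <- ws_phenotype_union("SEED", map)
  tab <- shared_phenotype_counts(c("G1", "G2", "G3"), pws, map)
  expect_equal(tab$n_overlap, c(2L, 1L, 0L))
  expect_equal(tab$shared_terms[[1]], c("a", "b"))
  expect_equal(tab$shared_terms[[3]], character(0))
  expect_equal(attr(tab, "total_shared_terms"), 2L)
})
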