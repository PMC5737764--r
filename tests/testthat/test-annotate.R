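test_that("expression entropy matches closed forms and scale invariance", {
  expect_equal(expression_entropy(rep(3.7, 25)), log2(25))
  expect_equal(expression_entropy(c(5, rep(0, 24))), 0)
  expect_equal(expression_entropy(c(2, 2, rep(0, 23))), 1)
  set.seed(1)
  x <- runif(25)
  expect_equal(expression_entropy(x), expression_entropy(17.3 * x))
  expect_lt(expression_entropy(x), log2(25))
  expect_true(is.na(expression_entropy(rep(0, 25))))
  expect_error(expression_entropy(c(1, -2)), "negative",
               class = "varmoi_validation_error")
})

test_that("average heterozygosity sums 2pq over SNPs divided by length", {
  expect_equal(average_heterozygosity(0.5, 0.5, 1000), 5e-4)
  expect_equal(average_heterozygosity(numeric(), numeric(), 500), 0)
  expect_equal(average_heterozygosity(c(0.1, 0.2), c(0.9, 0.8), 100), 0.005)
  expect_error(average_heterozygosity(0.1, 0.9, 0), "positive",
               class = "varmoi_validation_error")
  expect_error(average_heterozygosity(1.2, 0.5, 10), "\\[0, 1\\]",
               class = "varmoi_validation_error")
  # linearity: concatenating disjoint SNP lists sums the numerators
  set.seed(2)
  for (i in 1:10) {
    p1 <- runif(5, 0, 0.5); q1 <- 1 - p1
    p2 <- runif(3, 0, 0.5); q2 <- 1 - p2
    expect_equal(average_heterozygosity(c(p1, p2), c(q1, q2), 800),
                 average_heterozygosity(p1, q1, 800) +
                   average_heterozygosity(p2, q2, 800))
  }
})

test_that("snp density is count over coding length", {
  expect_equal(snp_density(5, 1000), 0.005)
  expect_equal(snp_density(0, 1000), 0)
  expect_equal(snp_density(3, 300), 0.01)
  expect_error(snp_density(1, 0), "positive",
               class = "varmoi_validation_error")
})

test_that("shortest path to a gene set matches a hand BFS oracle", {
  edges <- rbind(c("A", "B"), c("B", "C"))
  net <- igraph::graph_from_data_frame(as.data.frame(edges),
                                       directed = FALSE)
  expect_equal(shortest_path_to_set("C", "C", net), 0)
  expect_equal(shortest_path_to_set("A", "C", net), 2)
  net2 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "X"), to = c("B", "Y")), directed = FALSE)
  expect_true(is.na(shortest_path_to_set("A", "Y", net2)))
  expect_true(is.na(shortest_path_to_set("Z", "Y", net2)))
  # random graphs against the BFS oracle
  set.seed(3)
  for (i in 1:15) {
    nodes <- paste0("n", 1:10)
    e <- cbind(sample(nodes, 12, replace = TRUE),
               sample(nodes, 12, replace = TRUE))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    g <- igraph::simplify(igraph::graph_from_data_frame(
      as.data.frame(e), directed = FALSE, vertices = nodes))
    target <- sample(nodes, 2)
    from <- sample(nodes, 1)
    expect_equal(shortest_path_to_set(from, target, g),
                 bfs_dist(e, from, target))
  }
})

test_that("isoform flags report longest transcript and CDS coverage", {
  ex <- data.frame(
    transcript = c("G1.t1", "G1.t2"), gene = "G1", chrom = "chr1",
    strand = "+", start = c(10L, 10L), end = c(40L, 25L))
  models <- transcript_models(ex)
  one <- data.table::data.table(gene = "G1", transcript = "G1.t1")
  both <- data.table::data.table(gene = "G1",
                                 transcript = c("G1.t1", "G1.t2"))
  f1 <- transcript_flags(both, models)
  expect_equal(f1$is_longest, c(TRUE, FALSE))
  expect_equal(unique(f1$isoform_coverage), "full")
  f2 <- transcript_flags(one, models)
  expect_true(f2$is_longest)
  expect_equal(unique(f2$isoform_coverage), "partial")
})

test_that("annotation populates computed features even without site tables", {
  fx <- small_fixture()
  bare <- moi_resources(gene_table = fx$resources$gene_table,
                        gene_sets = fx$resources$gene_sets,
                        network = fx$resources$network,
                        polymorphisms = fx$resources$polymorphisms)
  v <- moi_variants(fx$pools$chrom[1:5], fx$pools$pos[1:5],
                    fx$pools$ref[1:5], fx$pools$alt[1:5])
  ann <- annotate_variants(v, bare, fx$reference)
  expect_true(all(is.na(ann$gerp_score)))
  expect_true(all(is.na(ann$af_panel)))
  expect_true(all(!is.na(ann$expr_entropy)))
  expect_true(all(!is.na(ann$syn_density)))
  expect_true(all(!is.na(ann$transcript_length)))
})

test_that("zero-missingness fixtures annotate with no missing fields", {
  fx <- small_fixture(seed = 21, missingness = c(gerp = 0, af = 0,
                                                 splice = 0, gene = 0))
  v <- moi_variants(fx$pools$chrom, fx$pools$pos, fx$pools$ref, fx$pools$alt)
  ann <- annotate_variants(v, fx$resources, fx$reference)
  cat_names <- attr(ann, "catalogue")$name
  na_counts <- vapply(cat_names, function(f) sum(is.na(ann[[f]])), numeric(1))
  expect_equal(sum(na_counts), 0, ignore_attr = TRUE)
})

test_that("synonymous-only variants yield zero annotation records", {
  ref <- hand_ref("+")
  fx <- small_fixture()
  v <- moi_variants("chr1", 16, "C", "T")  # GCC -> GCT, synonymous
  ann <- annotate_variants(v, fx$resources, ref)
  expect_equal(nrow(ann), 0L)
})

test_that("annotation is deterministic and input-order independent", {
  fx <- small_fixture()
  v1 <- moi_variants(fx$pools$chrom, fx$pools$pos, fx$pools$ref,
                     fx$pools$alt)
  perm <- rev(seq_len(nrow(v1)))
  v2 <- moi_variants(fx$pools$chrom[perm], fx$pools$pos[perm],
                     fx$pools$ref[perm], fx$pools$alt[perm])
  a1 <- annotate_variants(v1, fx$resources, fx$reference)
  a2 <- annotate_variants(v2, fx$resources, fx$reference)
  key <- function(a) order(a$chrom, a$pos, a$alt, a$transcript)
  expect_equal(data.frame(a1)[key(a1), ], data.frame(a2)[key(a2), ],
               ignore_attr = TRUE)
})
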