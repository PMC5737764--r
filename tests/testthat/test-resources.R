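test_that("site tables parse, validate and look up with explicit missing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tgerp", "chr1\t100\t3.5", "chr2\t7\t."), f)
  st <- load_site_table(f, values = "gerp")
  expect_equal(varmoi:::site_lookup(st, "chr1", 100, col = "gerp"), 3.5)
  expect_true(is.na(varmoi:::site_lookup(st, "chr2", 7, col = "gerp")))
  expect_true(is.na(varmoi:::site_lookup(st, "chr1", 999, col = "gerp")))

  writeLines("chrom\tpos\tgerp", f)
  empty <- load_site_table(f, values = "gerp")
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(varmoi:::site_lookup(empty, "chr1", 1, col = "gerp")))

  writeLines(c("chrom\tpos\talt\taf", "chr1\t5\tG\t1.5"), f)
  expect_error(load_site_table(f, values = "af", af_cols = "af"),
               "outside \\[0,1\\]", class = "varmoi_validation_error")
  writeLines(c("chrom\tpos\tgerp", "chr1\tx9\t1.0"), f)
  expect_error(load_site_table(f, values = "gerp"), "line 2",
               class = "varmoi_validation_error")
  writeLines(c("chrom\tpos\tgerp", "chr1\t5\t1", "chr1\t5\t2"), f)
  expect_error(load_site_table(f, values = "gerp"), "duplicate",
               class = "varmoi_validation_error")
})

test_that("network loader collapses duplicate undirected edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene1\tgene2", "A\tB", "B\tA"), f)
  g <- load_network(f)
  expect_equal(igraph::ecount(g), 1)
  writeLines(c("gene1\tgene2", "A\tB", "B\tC"), f)
  g <- load_network(f)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_error(load_network("/nonexistent/file.tsv"), "not found",
               class = "varmoi_validation_error")
  writeLines(c("gene1\tgene2", "A\t"), f)
  expect_error(load_network(f), "blank", class = "varmoi_validation_error")
})

test_that("interval tracks enforce half-open, non-empty intervals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript\tstart\tend\tcategory", "t1\t5\t10\tpfam"), f)
  tr <- load_interval_track(f, "protein", categories = c("pfam", "smart"))
  # start <= pos < end
  expect_equal(varmoi:::track_hit(tr, "t1", c(4, 5, 9, 10), "pfam"),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_false(varmoi:::track_hit(tr, "t1", 6, "smart"))
  writeLines(c("transcript\tstart\tend\tcategory", "t1\t10\t10\tpfam"), f)
  expect_error(load_interval_track(f, "protein"), "interval",
               class = "varmoi_validation_error")
  writeLines(c("transcript\tstart\tend\tcategory", "t1\t1\t5\tweird"), f)
  expect_error(load_interval_track(f, "protein", categories = "pfam"),
               "unknown categories", class = "varmoi_validation_error")
})

test_that("every generated resource round-trips through its writer/loader", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  write_resources(fx$resources, dir)
  back <- load_resources(dir)
  orig <- fx$resources
  for (nm in c("gerp_sites", "af_sites", "splice_sites")) {
    a <- data.frame(orig[[nm]]); b <- data.frame(back[[nm]])
    expect_equal(b[order(b$chrom, b$pos), ], a[order(a$chrom, a$pos), ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  for (nm in c("gerp_elements", "domains", "ptms", "disorder",
               "mirna_sites")) {
    a <- data.frame(orig[[nm]]); b <- data.frame(back[[nm]])
    expect_equal(b[do.call(order, b), ], a[do.call(order, a), ],
                 ignore_attr = TRUE)
  }
  expect_equal(data.frame(back$gene_table), data.frame(orig$gene_table),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_setequal(names(back$gene_sets), names(orig$gene_sets))
  for (nm in names(orig$gene_sets))
    expect_equal(sort(back$gene_sets[[nm]]), sort(orig$gene_sets[[nm]]))
  es <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(es(back$network), es(orig$network))
  a <- data.frame(orig$polymorphisms); b <- data.frame(back$polymorphisms)
  expect_equal(b[do.call(order, b), ], a[do.call(order, a), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gene table and polymorphism invariants are enforced", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tpli", "G1\t1.2"), f)
  expect_error(load_gene_table(f), "pli", class = "varmoi_validation_error")
  writeLines(c("gene\tdnds_macaque", "G1\t-0.1"), f)
  expect_error(load_gene_table(f), "negative",
               class = "varmoi_validation_error")
  hdr <- "transcript\tsnp_class\tmaf\tref_af\tgerp\tin_element\tethnicity"
  writeLines(c(hdr, "t1\tsyn\t0.7\t0.3\t1\t1\tafr"), f)
  expect_error(load_polymorphism_table(f), "minor allele frequency",
               class = "varmoi_validation_error")
  writeLines(c(hdr, "t1\tsyn\t0.4\t0.9\t1\t1\tafr"), f)
  expect_error(load_polymorphism_table(f), "exceeds 1",
               class = "varmoi_validation_error")
})
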