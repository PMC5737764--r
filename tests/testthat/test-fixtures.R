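test_that("generated references satisfy their construction invariants", {
  fx <- small_fixture()
  ref <- fx$reference
  tx <- ref$models$tx
  expect_true(all(tx$cds_length %% 3 == 0))
  expect_setequal(unique(tx$strand), c("+", "-"))
  cds <- varmoi:::build_cds_index(ref)
  primary <- tx$transcript[grepl("\\.t1$", tx$transcript)]
  for (t in primary) {
    s <- cds$seqs[[t]]
    expect_equal(substr(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_true(tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
    expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  }
  # every gene present, class bookkeeping intact
  expect_equal(nrow(ref$genes), sum(tiny_config()$genes_per_class))
})

test_that("pool variants are genuine nonsynonymous changes at config sizes", {
  fx <- small_fixture()
  pools <- fx$pools
  cfg <- fx$config
  for (cl in names(cfg$variants_per_class))
    expect_equal(sum(pools$class == cl),
                 unname(cfg$variants_per_class[cl]), ignore_attr = TRUE)
  v <- moi_variants(pools$chrom, pools$pos, pools$ref, pools$alt)
  cc <- call_consequences(v, fx$reference)
  primary <- cc[grepl("\\.t1$", cc$transcript), ]
  expect_equal(nrow(primary), nrow(pools))
  expect_true(all(primary$effect == "nonsynonymous"))
})

test_that("identical seeds give byte-identical fixture files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- tiny_config()
  simulate_fixtures(cfg, seed = 33, dir = d1)
  simulate_fixtures(cfg, seed = 33, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  d3 <- withr::local_tempdir()
  simulate_fixtures(cfg, seed = 34, dir = d3)
  same <- vapply(files, function(f)
    identical(readBin(file.path(d1, f), "raw", 1e7),
              readBin(file.path(d3, f), "raw", 1e7)), logical(1))
  expect_false(all(same))
})

test_that("a written reference reloads to the same models and genome", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  write_reference(fx$reference, dir)
  back <- read_reference(file.path(dir, "genome.fa"),
                         file.path(dir, "models.gtf"))
  expect_identical(back$genome, fx$reference$genome)
  key <- function(m) {
    e <- data.frame(m$exons)[, c("transcript", "gene", "chrom", "strand",
                                 "start", "end")]
    e[order(e$transcript, e$start), ]
  }
  expect_equal(key(back$models), key(fx$reference$models),
               ignore_attr = TRUE)
  expect_equal(data.frame(back$models$tx[order(back$models$tx$transcript)]),
               data.frame(fx$reference$models$tx[
                 order(fx$reference$models$tx$transcript)]),
               ignore_attr = TRUE)
})

test_that("pools round-trip through VCF reading and label files", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  write_pools(fx$pools, dir)
  v <- read_variants(file.path(dir, "pools.vcf"))
  expect_equal(data.frame(v[order(v$chrom, v$pos, v$alt),
                            c("chrom", "pos", "ref", "alt")]),
               data.frame(fx$pools[order(fx$pools$chrom, fx$pools$pos,
                                         fx$pools$alt),
                                   c("chrom", "pos", "ref", "alt")]),
               ignore_attr = TRUE)
  p <- read_pools(dir)
  expect_setequal(p$class, unique(fx$pools$class))
})

test_that("multi-allelic and non-SNV records are handled on ingest", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t10\t.\tA\tG,T\t.\t.\t.",
               "chr1\t20\t.\tAT\tA\t.\t.\t.",
               "chr1\t30\t.\tC\tCG\t.\t.\t."), f)
  v <- read_variants(f)
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("G", "T"))
  expect_equal(attr(v, "skipped"), 2L)
})

test_that("zero separation leaves class-conditional distributions flat", {
  fx0 <- small_fixture(delta = 0, seed = 15,
                       genes = c(benign = 60, dominant = 60, recessive = 60),
                       variants = c(benign = 120, dominant = 120,
                                    recessive = 120))
  gt <- fx0$resources$gene_table
  cls <- fx0$reference$genes$class[match(gt$gene, fx0$reference$genes$gene)]
  pli_means <- tapply(gt$pli, cls, mean, na.rm = TRUE)
  expect_lt(max(pli_means) - min(pli_means), 0.15)
  g <- fx0$resources$gerp_sites
  vcls <- fx0$pools$class[match(paste(g$chrom, g$pos),
                                paste(fx0$pools$chrom, fx0$pools$pos))]
  gm <- tapply(g$gerp, vcls, mean)
  expect_lt(max(gm) - min(gm), 0.4)
})

test_that("class-hubbed gene sets pull dominant genes closer in the network", {
  fx <- small_fixture(delta = 3, seed = 16,
                      genes = c(benign = 60, dominant = 60, recessive = 60),
                      variants = c(benign = 120, dominant = 120,
                                   recessive = 120))
  genes <- fx$reference$genes
  d <- varmoi:::distances_to_set(genes$gene,
                                 fx$resources$gene_sets$dominant,
                                 fx$resources$network)
  mean_d <- tapply(d, genes$class, mean, na.rm = TRUE)
  expect_lt(mean_d[["dominant"]], mean_d[["benign"]])
})

test_that("the feature-matrix simulator matches its configuration", {
  fm <- simulate_feature_matrix(n_per_class = c(benign = 20, dominant = 30,
                                                recessive = 10),
                                n_signal = 4, n_noise = 7, delta = 2,
                                seed = 17)
  expect_equal(dim(fm$x), c(60, 11))
  expect_equal(as.vector(table(fm$labels)), c(20, 30, 10))
  expect_false(anyNA(fm$x))
  fm2 <- simulate_feature_matrix(n_per_class = c(benign = 20, dominant = 30,
                                                 recessive = 10),
                                 n_signal = 4, n_noise = 7, delta = 2,
                                 seed = 17)
  expect_identical(fm$x, fm2$x)
})
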