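# Shared fixture builders and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

tiny_config <- function(delta = 3,
                        genes = c(benign = 12, dominant = 8, recessive = 12),
                        variants = c(benign = 24, dominant = 24,
                                     recessive = 24), ...) {
  fixture_config(genes_per_class = genes, variants_per_class = variants,
                 delta = delta, ...)
}

small_fixture <- function(delta = 3, seed = 7, ...) {
  key <- paste(c("fx", delta, seed, unlist(list(...))), collapse = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_fixtures(tiny_config(delta, ...),
                                               seed = seed)
  .fixture_cache[[key]]
}

pool_labels <- function(ann, pools) {
  pools$class[match(paste(ann$chrom, ann$pos, ann$ref, ann$alt),
                    paste(pools$chrom, pools$pos, pools$ref, pools$alt))]
}

annotated_fixture <- function(delta = 3, seed = 7) {
  key <- paste("ann", delta, seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- small_fixture(delta, seed)
    v <- moi_variants(fx$pools$chrom, fx$pools$pos, fx$pools$ref,
                      fx$pools$alt)
    ann <- annotate_variants(v, fx$resources, fx$reference)
    .fixture_cache[[key]] <- list(fx = fx, ann = ann,
                                  labels = pool_labels(ann, fx$pools))
  }
  .fixture_cache[[key]]
}

# Minimal annotation-record table for sampling semantics tests: n_variants
# distributed as evenly as possible over n_genes, one transcript each.
fake_pool <- function(n_variants, n_genes) {
  gene <- sprintf("g%04d", rep(seq_len(n_genes),
                               length.out = n_variants))
  gene <- sort(gene)
  data.table::data.table(
    chrom = "chr1", pos = seq_len(n_variants) * 10L,
    ref = "A", alt = "G", gene = gene,
    transcript = paste0(gene, ".t1"),
    transcript_length = 300)
}

# Independent consequence oracle: rebuild the mutated genome, extract the
# CDS with Biostrings interval/strand arithmetic, translate the whole
# protein before and after, and diff.
oracle_consequence <- function(ref, tx_id, variant) {
  ex <- ref$models$exons
  e <- ex[ex$transcript == tx_id, ]
  e <- e[order(e$start), ]
  chrom <- e$chrom[1]
  gseq <- ref$genome[[chrom]]
  stopifnot(substr(gseq, variant$pos, variant$pos) == variant$ref)
  mut <- gseq
  substr(mut, variant$pos, variant$pos) <- variant$alt
  extract <- function(s) {
    parts <- substring(s, e$start + 1L, e$end)
    cds <- paste(parts, collapse = "")
    if (e$strand[1] == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    cds
  }
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(extract(gseq)),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(extract(mut)),
                                           no.init.codon = TRUE))
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  if (!length(d))
    return(list(effect = "synonymous", protein_pos = NA, aa_ref = NA,
                aa_alt = NA))
  aa0 <- substr(p0, d[1], d[1]); aa1 <- substr(p1, d[1], d[1])
  effect <- if (aa1 == "*") "stop-gained" else if (aa0 == "*") "stop-lost"
  else "nonsynonymous"
  list(effect = effect, protein_pos = d[1], aa_ref = aa0, aa_alt = aa1)
}

# Hand reference: one gene, CDS ATG GCC TAA (M A *), single exon at
# 0-based [10, 19) on chr1.
hand_ref <- function(strand) {
  cds <- "ATGGCCTAA"
  exon_seq <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome <- c(chr1 = paste0("GATTACAGAT", exon_seq, "CCGGA"))
  ex <- data.frame(transcript = "T1.t1", gene = "G1", chrom = "chr1",
                   strand = strand, start = 10L, end = 19L)
  moi_reference(genome, transcript_models(ex))
}

# Hand BFS over an edge list (shortest-path oracle).
bfs_dist <- function(edges, from, to_set) {
  if (from %in% to_set) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- from; frontier <- from; d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (!length(nxt)) return(NA_real_)
    if (any(nxt %in% to_set)) return(d)
    seen <- c(seen, nxt); frontier <- nxt
  }
  NA_real_
}

# Exact pairwise-comparison two-class AUC (ties count half).
brute_auc <- function(score, is_pos) {
  pos <- score[is_pos]; neg <- score[!is_pos]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}
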