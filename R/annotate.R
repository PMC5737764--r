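## Feature computation for nonsynonymous consequences.

#' Average heterozygosity of a SNP list
#'
#' Sum over SNPs of the per-site heterozygosity kernel 2pq, divided by the
#' coding transcript length l: sum_i 2 p_i q_i / l, where p is the minor
#' allele frequency and q the reference allele frequency.  An empty SNP
#' list gives 0.
#'
#' @param p minor allele frequencies in [0, 1].
#' @param q reference allele frequencies in [0, 1].
#' @param l coding transcript length in bases (> 0).
#' @return numeric scalar.
#' @export
average_heterozygosity <- function(p, q, l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l <= 0)
    stop_validation("coding length l must be a positive number, got %s",
                    format(l))
  if (length(p) != length(q))
    stop_validation("p and q must have equal length")
  if (length(p) && (any(p < 0 | p > 1, na.rm = TRUE) ||
                    any(q < 0 | q > 1, na.rm = TRUE)))
    stop_validation("allele frequencies must lie in [0, 1]")
  if (!length(p)) return(0)
  sum(2 * p * q) / l
}

#' Shannon entropy of a tissue expression profile
#'
#' The per-tissue mean expression vector is normalized to proportions and
#' the base-2 Shannon entropy is returned, with 0 * log(0) taken as 0.
#' Maximal (log2 of the tissue count) for uniform expression, 0 for
#' expression confined to one tissue.  An all-zero or incomplete (NA)
#' vector yields NA (missing).
#'
#' @param expr non-negative per-tissue mean expression values.
#' @return entropy in bits, or NA.
#' @export
expression_entropy <- function(expr) {
  if (!length(expr) || anyNA(expr)) return(NA_real_)
  if (any(expr < 0))
    stop_validation("negative expression value: %g", min(expr))
  tot <- sum(expr)
  if (tot == 0) return(NA_real_)
  p <- expr / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shortest path from a gene to a gene set
#'
#' Unweighted shortest-path distance from \code{gene} to the nearest member
#' of \code{target}: 0 when the gene itself is a member, NA when the gene
#' is absent from the network or no member is reachable.
#'
#' @param gene gene symbol.
#' @param target character vector of member symbols.
#' @param net igraph interaction network.
#' @return non-negative integer distance or NA.
#' @export
shortest_path_to_set <- function(gene, target, net) {
  distances_to_set(gene, target, net)
}

## Vectorized over genes.
distances_to_set <- function(genes, target, net) {
  out <- rep(NA_real_, length(genes))
  out[genes %in% target] <- 0
  todo <- which(is.na(out))
  if (!length(todo) || is.null(net)) return(out)
  vs <- igraph::V(net)$name
  present <- intersect(unique(genes[todo]), vs)
  members <- intersect(target, vs)
  if (length(present) && length(members)) {
    d <- igraph::distances(net, v = present, to = members)
    dmin <- apply(d, 1, min)
    dmin[!is.finite(dmin)] <- NA_real_
    hit <- match(genes[todo], present)
    out[todo] <- dmin[hit]
  }
  out
}

#' Synonymous/nonsynonymous SNP density
#'
#' @param n SNP count (>= 0).
#' @param l coding transcript length in bases (> 0).
#' @return n / l.
#' @export
snp_density <- function(n, l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l <= 0)
    stop_validation("coding length l must be a positive number, got %s",
                    format(l))
  if (n < 0) stop_validation("SNP count must be non-negative")
  n / l
}

#' Isoform flags for a variant's consequences
#'
#' Given all consequences of one variant within one gene, reports per
#' record whether its transcript is the gene's longest isoform (ties broken
#' toward the lexicographically smallest transcript id) and whether the
#' variant hits the CDS of every isoform of the gene (\code{"full"}) or
#' only some (\code{"partial"}).
#'
#' @param consequences \code{moi_consequences} rows of one variant in one
#'   gene.
#' @param models \code{transcript_models} (for the gene's full isoform
#'   inventory).
#' @return data.table with columns \code{transcript}, \code{is_longest},
#'   \code{isoform_coverage}.
#' @export
transcript_flags <- function(consequences, models) {
  cons <- data.table::as.data.table(consequences)
  if (!nrow(cons)) stop_validation("no consequences given")
  gene <- cons$gene[1]
  iso <- models$tx[models$tx$gene == gene, ]
  longest <- iso$transcript[order(-iso$cds_length, iso$transcript)][1]
  coverage <- if (length(unique(cons$transcript)) == nrow(iso))
    "full" else "partial"
  data.table(transcript = cons$transcript,
             is_longest = cons$transcript == longest,
             isoform_coverage = coverage)
}

## Polymorphism-table aggregates per transcript.  With a loaded table,
## counts and heterozygosities are defined (0) for SNP-free transcripts
## while mean-GERP and percent-in-element stay missing (empty mean).
poly_features <- function(poly, tx, ethnicities) {
  het_cols <- c(paste0("het_syn_", ethnicities),
                paste0("het_nonsyn_", ethnicities))
  out <- data.table(transcript = tx$transcript, l = tx$cds_length,
                    syn_density = NA_real_, nonsyn_density = NA_real_,
                    syn_mean_gerp = NA_real_, nonsyn_mean_gerp = NA_real_,
                    pct_syn_in_elements = NA_real_,
                    pct_nonsyn_in_elements = NA_real_)
  for (h in het_cols) out[, (h) := NA_real_]
  if (is.null(poly)) { out[, "l" := NULL]; return(out) }
  for (cl in c("syn", "nonsyn")) {
    out[, (paste0(cl, "_density")) := 0]
    for (h in paste0("het_", cl, "_", ethnicities)) out[, (h) := 0]
  }
  p <- data.table::as.data.table(poly)
  p <- merge(p, out[, c("transcript", "l"), with = FALSE], by = "transcript")
  if (nrow(p)) {
    agg <- p[, list(n = .N,
                    mean_gerp = mean(.SD$gerp, na.rm = TRUE),
                    pct_elem = 100 * mean(.SD$in_element, na.rm = TRUE)),
             by = c("transcript", "snp_class")]
    het <- p[, list(het = sum(2 * .SD$maf * .SD$ref_af) / .SD$l[1]),
             by = c("transcript", "snp_class", "ethnicity")]
    for (cl in c("syn", "nonsyn")) {
      a <- agg[agg$snp_class == cl, ]
      m <- match(out$transcript, a$transcript)
      out[, (paste0(cl, "_density")) :=
            ifelse(is.na(m), 0, a$n[m] / out$l)]
      out[, (paste0(cl, "_mean_gerp")) := a$mean_gerp[m]]
      out[, (paste0("pct_", cl, "_in_elements")) := a$pct_elem[m]]
      for (eth in ethnicities) {
        sel_h <- het$snp_class == cl & het$ethnicity == eth
        h <- het[sel_h, ]
        mh <- match(out$transcript, h$transcript)
        out[, (paste0("het_", cl, "_", eth)) :=
              ifelse(is.na(mh), 0, h$het[mh])]
      }
    }
  }
  out[, "l" := NULL]
  out
}

## Percent of the transcript CDS covered by GERP elements.
pct_cds_in_elements <- function(track, models, transcripts) {
  out <- rep(NA_real_, length(transcripts))
  if (is.null(track)) return(out)
  tr <- data.table::as.data.table(track)
  ex <- models$exons
  for (i in seq_along(transcripts)) {
    e <- ex[ex$transcript == transcripts[i], ]
    el <- tr[tr$chrom %in% e$chrom, ]
    cov <- 0L
    if (nrow(el)) {
      for (j in seq_len(nrow(e))) {
        o <- pmin(el$end, e$end[j]) - pmax(el$start, e$start[j])
        cov <- cov + sum(pmax(o, 0L))
      }
    }
    out[i] <- 100 * cov / sum(e$end - e$start)
  }
  out
}

#' Annotate variants with the full feature catalogue
#'
#' Calls consequences against the transcript models and, for every
#' nonsynonymous (variant, transcript) pair, computes or looks up each
#' feature in the catalogue.  A feature whose resource has no entry for the
#' record is emitted as missing (NA); computed features (entropy, density,
#' flags from loaded tracks) are always populated.
#'
#' @param variants \code{moi_variants} table.
#' @param resources \code{moi_resources} bundle.
#' @param ref \code{moi_reference}.
#' @param catalogue feature catalogue; fixed for all records.
#' @param cds optional precomputed CDS index.
#' @return data.table of class \code{"moi_annotations"}: identification
#'   columns (chrom, pos, ref, alt, gene, transcript, protein_pos, aa_ref,
#'   aa_alt) followed by one column per catalogue feature.
#' @export
annotate_variants <- function(variants, resources, ref,
                              catalogue = default_catalogue(), cds = NULL) {
  validate_catalogue(catalogue)
  if (is.null(cds)) cds <- build_cds_index(ref)
  cons <- call_consequences(variants, ref, cds = cds)
  ns <- cons[cons$effect == "nonsynonymous", ]
  id_cols <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
               "protein_pos", "aa_ref", "aa_alt")
  rec <- data.table::as.data.table(ns)[, id_cols, with = FALSE]
  tl <- ns$transcript_length
  if (!nrow(rec)) {
    for (f in catalogue$name) rec[, (f) := numeric()]
    return(structure(rec, class = c("moi_annotations", class(rec)),
                     catalogue = catalogue))
  }
  res <- resources
  pops <- attr(catalogue, "populations")
  eths <- attr(catalogue, "ethnicities")
  flag_or_na <- function(track, key, pos, category = NULL) {
    if (is.null(track)) return(rep(NA, nrow(rec)))
    track_hit(track, key, pos, category)
  }

  rec[, "gerp_score" := site_lookup(res$gerp_sites, rec$chrom, rec$pos,
                                    col = "gerp")]
  rec[, "in_gerp_element" := flag_or_na(res$gerp_elements, rec$chrom,
                                        rec$pos - 1L)]
  ## gene-level block
  gt <- res$gene_table
  gene_col <- function(col) {
    if (is.null(gt) || !col %in% names(gt)) return(rep(NA_real_, nrow(rec)))
    gt[[col]][match(rec$gene, gt$gene)]
  }
  rec[, "dnds_macaque" := gene_col("dnds_macaque")]
  rec[, "dnds_mouse" := gene_col("dnds_mouse")]
  for (col in c("af_panel", paste0("af_panel_", pops), "af_esp", "af_exac"))
    rec[, (col) := site_lookup(res$af_sites, rec$chrom, rec$pos,
                               alt = rec$alt, col = col)]
  rec[, "pli" := gene_col("pli")]
  for (cat in attr(catalogue, "domain_categories"))
    rec[, (paste0("in_", cat)) := flag_or_na(res$domains, rec$transcript,
                                             rec$protein_pos, cat)]
  for (tp in attr(catalogue, "ptm_types"))
    rec[, (paste0("ptm_", tp)) := flag_or_na(res$ptms, rec$transcript,
                                             rec$protein_pos, tp)]
  rec[, "disordered" := flag_or_na(res$disorder, rec$transcript,
                                   rec$protein_pos)]
  rec[, "mirna_site" := flag_or_na(res$mirna_sites, rec$chrom, rec$pos - 1L)]
  rec[, "splice_score" := site_lookup(res$splice_sites, rec$chrom, rec$pos,
                                      col = "splice_score")]
  ## network block
  sets <- res$gene_sets
  rec[, "dist_dominant" := distances_to_set(rec$gene,
                                            sets$dominant %||% character(),
                                            res$network)]
  rec[, "dist_recessive" := distances_to_set(rec$gene,
                                             sets$recessive %||% character(),
                                             res$network)]
  for (nw in attr(catalogue, "networks"))
    rec[, (paste0("centrality_", nw)) := gene_col(paste0("centrality_", nw))]
  expr_cols <- sprintf("expr_t%02d", seq_len(attr(catalogue, "tissues")))
  for (col in expr_cols) rec[, (col) := gene_col(col)]
  if (!is.null(gt) && all(expr_cols %in% names(gt))) {
    em <- as.matrix(gt[, expr_cols, with = FALSE])
    ent <- apply(em, 1, expression_entropy)
    rec[, "expr_entropy" := ent[match(rec$gene, gt$gene)]]
  } else rec[, "expr_entropy" := NA_real_]
  ## gene/transcript block
  rec[, "transcript_length" := as.numeric(tl)]
  ## vectorized isoform flags (transcript_flags() is the per-variant form)
  tx_all <- ref$models$tx
  longest_by_gene <- tx_all[order(-tx_all$cds_length, tx_all$transcript),
                            list(longest = .SD$transcript[1]), by = "gene"]
  n_iso <- tx_all[, list(n_iso = .N), by = "gene"]
  rec[, "is_longest" := rec$transcript ==
        longest_by_gene$longest[match(rec$gene, longest_by_gene$gene)]]
  key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, rec$gene)
  nhit <- stats::ave(as.integer(!duplicated(paste(key, rec$transcript))),
                     key, FUN = sum)
  rec[, "isoform_coverage" :=
        ifelse(nhit == n_iso$n_iso[match(rec$gene, n_iso$gene)],
               "full", "partial")]
  rec[, "seg_dup" := as.logical(gene_col("seg_dup"))]
  rec[, "pseudogene" := as.logical(gene_col("pseudogene"))]
  rec[, "paralog" := as.logical(gene_col("paralog"))]
  ## polymorphism/density block
  utx <- unique(rec$transcript)
  txs <- ref$models$tx[match(utx, ref$models$tx$transcript), ]
  pf <- poly_features(res$polymorphisms, txs, eths)
  mtx <- match(rec$transcript, pf$transcript)
  for (col in setdiff(names(pf), "transcript"))
    rec[, (col) := pf[[col]][mtx]]
  pct <- pct_cds_in_elements(res$gerp_elements, ref$models, utx)
  rec[, "pct_transcript_in_elements" := pct[match(rec$transcript, utx)]]

  data.table::setcolorder(rec, c(id_cols, catalogue$name))
  structure(rec, class = c("moi_annotations", class(rec)),
            catalogue = catalogue)
}

#' Write / read an annotation table
#'
#' Tab-delimited, one row per (variant, transcript), columns fixed by the
#' catalogue, '.' for missing; flags as 1/0.
#'
#' @param annotations \code{moi_annotations} table.
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  dt <- data.table::copy(data.table::as.data.table(annotations))
  for (col in names(dt)) if (is.logical(dt[[col]]))
    dt[, (col) := as.integer(dt[[col]])]
  write_tsv(dt, path)
}

#' @rdname write_annotations
#' @param catalogue feature catalogue the file was written under.
#' @export
read_annotations <- function(path, catalogue = default_catalogue()) {
  dt <- read_tsv(path)
  miss <- setdiff(catalogue$name, names(dt))
  if (length(miss))
    stop_validation("%s: catalogue features absent: %s", path,
                    paste(head(miss, 5), collapse = ", "))
  for (f in catalogue$name[catalogue$type == "flag"])
    dt[, (f) := as.logical(dt[[f]])]
  structure(dt, class = c("moi_annotations", class(dt)),
            catalogue = catalogue)
}
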