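## Sequence-based consequence calling against the transcript models.

EFFECT_CLASSES <- c("nonsynonymous", "synonymous", "stop-gained",
                    "stop-lost", "non-coding")

#' Call transcript-level consequences for variants
#'
#' For every transcript whose CDS contains the variant position, the
#' affected codon is identified respecting strand, reference and alternate
#' amino acids are translated under the standard codon table, and an effect
#' class is assigned: \code{nonsynonymous}, \code{synonymous},
#' \code{stop-gained}, \code{stop-lost}.  A variant outside every CDS
#' yields one \code{non-coding} row with NA transcript.
#'
#' @param variants \code{moi_variants} table.
#' @param ref \code{moi_reference} (genome + transcript models).
#' @param cds optional precomputed CDS index from
#'   \code{varmoi:::build_cds_index(ref)}; built on the fly otherwise.
#' @return data.table of class \code{"moi_consequences"}: one row per
#'   (variant, overlapping transcript) with protein position (1-based codon
#'   index), amino-acid change and effect class.
#' @export
call_consequences <- function(variants, ref, cds = NULL) {
  v <- data.table::as.data.table(variants)
  if (!nrow(v)) stop_validation("no variants")
  genome <- ref$genome
  bad <- which(!(v$chrom %in% names(genome)))
  if (length(bad))
    stop_validation("variant %s:%d: chromosome not in reference",
                    v$chrom[bad[1]], v$pos[bad[1]])
  bad <- which(v$pos > nchar(genome)[match(v$chrom, names(genome))])
  if (length(bad))
    stop_validation("variant %s:%d: position beyond chromosome end",
                    v$chrom[bad[1]], v$pos[bad[1]])
  gbase <- substring(genome[v$chrom], v$pos, v$pos)
  bad <- which(gbase != v$ref)
  if (length(bad))
    stop_validation(
      "reference mismatch at %s:%d: file says %s, genome has %s",
      v$chrom[bad[1]], v$pos[bad[1]], v$ref[bad[1]], gbase[bad[1]])

  if (is.null(cds)) cds <- build_cds_index(ref)
  v2 <- data.table::copy(v)
  v2[, "vid" := seq_len(.N)]
  hit <- cds$index[v2, on = c(chrom = "chrom", gpos = "pos"), nomatch = NULL,
                   allow.cartesian = TRUE]
  ## hit: chrom, gpos, transcript, strand, cds_pos, ref, alt, vid
  out_list <- list()
  if (nrow(hit)) {
    seqs <- cds$seqs[hit$transcript]
    cpos <- hit$cds_pos
    codon_idx <- (cpos - 1L) %/% 3L + 1L
    offset <- (cpos - 1L) %% 3L + 1L
    codon <- substring(seqs, 3L * codon_idx - 2L, 3L * codon_idx)
    alt_cds <- ifelse(hit$strand == "-", chartr("ACGT", "TGCA", hit$alt),
                      hit$alt)
    alt_codon <- codon
    substr(alt_codon, offset, offset) <- alt_cds
    code <- Biostrings::GENETIC_CODE
    aa_ref <- unname(code[codon])
    aa_alt <- unname(code[alt_codon])
    effect <- ifelse(aa_ref == aa_alt, "synonymous",
              ifelse(aa_alt == "*", "stop-gained",
              ifelse(aa_ref == "*", "stop-lost", "nonsynonymous")))
    tx <- ref$models$tx
    m <- match(hit$transcript, tx$transcript)
    out_list$coding <- data.table(
      chrom = hit$chrom, pos = hit$gpos, ref = hit$ref, alt = hit$alt,
      gene = tx$gene[m], transcript = hit$transcript,
      strand = hit$strand, protein_pos = codon_idx,
      aa_ref = aa_ref, aa_alt = aa_alt, effect = effect,
      transcript_length = tx$cds_length[m], vid = hit$vid)
  }
  nohit <- v2[!v2$vid %in% (if (nrow(hit)) hit$vid else integer()), ]
  if (nrow(nohit)) {
    out_list$noncoding <- data.table(
      chrom = nohit$chrom, pos = nohit$pos, ref = nohit$ref,
      alt = nohit$alt, gene = NA_character_, transcript = NA_character_,
      strand = NA_character_, protein_pos = NA_integer_,
      aa_ref = NA_character_, aa_alt = NA_character_,
      effect = "non-coding", transcript_length = NA_integer_,
      vid = nohit$vid)
  }
  out <- data.table::rbindlist(out_list)
  data.table::setorder(out, vid, transcript, na.last = TRUE)
  out[, "vid" := NULL]
  structure(out, class = c("moi_consequences", class(out)))
}
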