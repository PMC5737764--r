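## Reference genome and transcript models.
##
## Genomic coordinates are half-open 0-based internally; GTF (1-based,
## inclusive) and VCF (1-based) positions are converted on ingest.

#' Build transcript models from a CDS exon table
#'
#' @param exons data.frame with columns \code{transcript}, \code{gene},
#'   \code{chrom}, \code{strand} (\code{"+"}/\code{"-"}), \code{start},
#'   \code{end} (0-based half-open genomic CDS intervals).
#' @return list of class \code{"transcript_models"} with elements
#'   \code{tx} (per-transcript summary incl. coding length) and
#'   \code{exons} (exon table ranked in 5'-to-3' transcription order).
#' @export
transcript_models <- function(exons) {
  ex <- data.table::as.data.table(exons)
  need <- c("transcript", "gene", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    stop_validation("exon table missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (any(ex$start >= ex$end))
    stop_validation("exon with start >= end")
  data.table::setorder(ex, transcript, start)
  ## transcription order: ascending genomic for '+', descending for '-'
  ex[, "rank" := if (.SD$strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = "transcript"]
  ## non-overlap within transcript
  ov <- ex[, any(head(sort(.SD$end), -1) > tail(sort(.SD$start), -1)),
           by = "transcript"]
  if (any(ov$V1))
    stop_validation("overlapping CDS exons in transcript %s",
                    ov$transcript[which(ov$V1)[1]])
  tx <- ex[, list(gene = .SD$gene[1], chrom = .SD$chrom[1],
                  strand = .SD$strand[1],
                  cds_length = sum(.SD$end - .SD$start)),
           by = "transcript"]
  bad <- which(tx$cds_length %% 3L != 0L)
  if (length(bad))
    stop_validation("CDS length of %s (%d) not divisible by 3",
                    tx$transcript[bad[1]], tx$cds_length[bad[1]])
  structure(list(tx = tx, exons = ex), class = "transcript_models")
}

#' Read a reference genome and transcript models
#'
#' @param fasta path to the genome FASTA.
#' @param gtf path to transcript models in GTF format; rows with feature
#'   type \code{CDS} and \code{gene_id}/\code{transcript_id} attributes are
#'   used.
#' @return list of class \code{"moi_reference"} with \code{genome}
#'   (named character vector of chromosome sequences) and \code{models}.
#' @export
read_reference <- function(fasta, gtf) {
  if (!file.exists(fasta)) stop_validation("file not found: %s", fasta)
  if (!file.exists(gtf)) stop_validation("file not found: %s", gtf)
  dss <- Biostrings::readDNAStringSet(fasta)
  genome <- as.character(dss)
  names(genome) <- sub("\\s.*$", "", names(dss))
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", ]
  if (!nrow(df)) stop_validation("%s: no CDS features", gtf)
  ex <- data.table(transcript = as.character(df$transcript_id),
                   gene = as.character(df$gene_id),
                   chrom = as.character(df$seqnames),
                   strand = as.character(df$strand),
                   start = as.integer(df$start) - 1L,
                   end = as.integer(df$end))
  moi_reference(genome, transcript_models(ex))
}

#' @rdname read_reference
#' @param genome named character vector (or DNAStringSet) of chromosomes.
#' @param models a \code{transcript_models} object.
#' @param genes optional per-gene metadata (fixture generator bookkeeping).
#' @export
moi_reference <- function(genome, models, genes = NULL) {
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- as.character(genome)
    names(genome) <- nm
  }
  structure(list(genome = genome, models = models, genes = genes),
            class = "moi_reference")
}

#' Write a reference to FASTA + GTF
#'
#' @param ref an \code{moi_reference}.
#' @param dir output directory; writes \code{genome.fa} and
#'   \code{models.gtf}.
#' @return the directory, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dss <- Biostrings::DNAStringSet(ref$genome)
  Biostrings::writeXStringSet(dss, file.path(dir, "genome.fa"), width = 70L)
  ex <- data.table::copy(ref$models$exons)
  data.table::setorder(ex, transcript, rank)
  ## GTF frame: bases of the codon left incomplete by preceding exons
  ex[, "cum" := cumsum(c(0L, head(.SD$end - .SD$start, -1))),
     by = "transcript"]
  lines <- sprintf(
    "%s\tvarmoi\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$chrom, ex$start + 1L, ex$end, ex$strand, (3L - ex$cum %% 3L) %% 3L,
    ex$gene, ex$transcript)
  writeLines(lines, file.path(dir, "models.gtf"))
  invisible(dir)
}

## Per-transcript CDS geometry: genomic position of each coding base in
## 5'->3' order plus the coding-strand CDS sequence.  Returns
## list(index = data.table(chrom, gpos, transcript, cds_pos),
##      seqs  = named character CDS sequences).
build_cds_index <- function(ref) {
  ex <- ref$models$exons
  genome <- ref$genome
  pieces <- vector("list", nrow(ex))
  ord <- order(ex$transcript, ex$rank)
  exo <- ex[ord, ]
  for (i in seq_len(nrow(exo))) {
    s <- exo$start[i]; e <- exo$end[i]
    gpos <- (s + 1L):e
    if (exo$strand[i] == "-") gpos <- rev(gpos)
    pieces[[i]] <- gpos
  }
  lens <- lengths(pieces)
  index <- data.table(chrom = rep(exo$chrom, lens),
                      gpos = unlist(pieces),
                      transcript = rep(exo$transcript, lens),
                      strand = rep(exo$strand, lens))
  index[, "cds_pos" := seq_len(.N), by = "transcript"]
  ## coding-strand base at each position
  base <- substring(genome[index$chrom], index$gpos, index$gpos)
  base <- ifelse(index$strand == "-", chartr("ACGT", "TGCA", base), base)
  seqs <- vapply(split(base, index$transcript),
                 paste, character(1), collapse = "")
  data.table::setkeyv(index, c("chrom", "gpos"))
  list(index = index, seqs = seqs)
}
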