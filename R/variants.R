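## Variant input.
##
## Accepted inputs: VCF 4.x, or any header-bearing tab-delimited file with
## at least #CHROM, POS, REF and ALT columns (the VCF column body).
## Multi-allelic records are decomposed into biallelic variants on ingest;
## non-SNV alleles (indels, MNVs) are out of scope and dropped with a count.

BASES <- c("A", "C", "G", "T")

#' Construct a variant table
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt single reference/alternate bases (A/C/G/T).
#' @param ... further per-variant columns carried along (e.g. \code{gene}).
#' @return data.table of class \code{"moi_variants"}.
#' @export
moi_variants <- function(chrom, pos, ref, alt, ...) {
  v <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt), ...)
  if (nrow(v)) {
    if (any(v$pos < 1L | is.na(v$pos)))
      stop_validation("variant positions must be positive integers")
    bad <- which(!(v$ref %in% BASES) | !(v$alt %in% BASES))
    if (length(bad))
      stop_validation("variant %s:%d %s>%s: ref/alt must be single bases",
                      v$chrom[bad[1]], v$pos[bad[1]], v$ref[bad[1]],
                      v$alt[bad[1]])
    bad <- which(v$ref == v$alt)
    if (length(bad))
      stop_validation("variant %s:%d: ref equals alt (%s)",
                      v$chrom[bad[1]], v$pos[bad[1]], v$ref[bad[1]])
  }
  structure(v, class = c("moi_variants", class(v)))
}

#' Read variants from VCF or tab-delimited input
#'
#' \code{##} meta lines are skipped; the header line may start with
#' \code{#CHROM} (VCF) or \code{chrom}.  Multi-allelic ALT entries
#' (comma-separated) are decomposed into one biallelic variant each.
#' Non-SNV alleles are dropped; the number dropped is recorded in the
#' \code{"skipped"} attribute.
#'
#' @param path input file.
#' @return \code{moi_variants} table.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines)) stop_validation("%s: no header line", path)
  lines[1] <- sub("^#", "", lines[1])
  dt <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, colClasses = "character")
  names(dt) <- tolower(names(dt))
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(dt))
  if (length(miss))
    stop_validation("%s: missing column(s): %s", path,
                    paste(toupper(miss), collapse = ", "))
  ## decompose multi-allelic ALT
  alts <- strsplit(dt$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  dt <- dt[rep(seq_len(nrow(dt)), n), ]
  dt[, "alt" := unlist(alts)]
  keep <- dt$ref %in% BASES & dt$alt %in% BASES & dt$ref != dt$alt
  skipped <- sum(!keep)
  dt <- dt[keep, ]
  v <- moi_variants(dt$chrom, dt$pos, dt$ref, dt$alt)
  attr(v, "skipped") <- skipped
  v
}

#' Write variants as a minimal VCF
#'
#' @param variants \code{moi_variants} table.
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=varmoi",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", variants$chrom, variants$pos,
                  variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
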