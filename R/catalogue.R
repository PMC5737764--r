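#' Feature catalogue
#'
#' The catalogue fixes, at configuration time, the names and types of every
#' feature an annotation record carries.  It is identical for all records of
#' a run, recorded inside every feature matrix and trained model, and models
#' refuse matrices built under a different catalogue.
#'
#' Feature families (defaults in parentheses):
#' \itemize{
#'   \item evolutionary: per-site GERP score, GERP-element membership, dN/dS
#'     versus macaque and mouse;
#'   \item allele frequency: reference-panel AF (global panel plus
#'     per-population columns), a second and third panel AF, and the gene
#'     loss-of-function constraint score pLI;
#'   \item functional: protein-domain membership flags (PFAM, SMART, SCOP,
#'     signal peptide, transmembrane helix), post-translational-modification
#'     flags per type, disordered-residue flag, miRNA-binding-site flag and a
#'     precomputed splice score;
#'   \item network/expression: shortest path to known dominant and recessive
#'     disease genes, centrality per network (metabolic, genetic, signaling),
#'     mean expression per tissue (25) and the Shannon entropy of the tissue
#'     profile;
#'   \item gene/transcript: coding length, longest-isoform flag, full/partial
#'     isoform coverage, segmental-duplication, pseudogene and paralog flags;
#'   \item polymorphism density: synonymous/nonsynonymous SNP density, mean
#'     GERP of each SNP class, percent of each class inside GERP elements,
#'     percent of the transcript covered by GERP elements, and average
#'     heterozygosity per ethnicity and SNP class.
#' }
#'
#' @param tissues number of tissues with per-tissue mean expression features.
#' @param populations population suffixes for per-population allele
#'   frequencies of the primary reference panel.
#' @param ethnicities ethnicity tags for per-ethnicity average
#'   heterozygosity features.
#' @param ptm_types post-translational modification categories flagged.
#' @param domain_categories protein domain categories flagged.
#' @param networks network names with a centrality feature each.
#' @return A data.frame with columns \code{name}, \code{type} (one of
#'   \code{"numeric"}, \code{"flag"}, \code{"categorical"}) and
#'   \code{levels} (comma-separated, categorical features only), with class
#'   \code{"moi_catalogue"}.
#' @export
default_catalogue <- function(tissues = 25,
                              populations = c("afr", "eur", "eas"),
                              ethnicities = c("afr", "eur", "eas"),
                              ptm_types = c("phosphorylation", "methylation",
                                            "acetylation", "ubiquitination"),
                              domain_categories = c("pfam", "smart", "scop",
                                                    "signal_peptide",
                                                    "transmembrane"),
                              networks = c("metabolic", "genetic",
                                           "signaling")) {
  num <- function(n) data.frame(name = n, type = "numeric", levels = NA_character_)
  flg <- function(n) data.frame(name = n, type = "flag", levels = NA_character_)
  cat_ <- function(n, lv) data.frame(name = n, type = "categorical",
                                     levels = paste(lv, collapse = ","))
  spec <- rbind(
    num(c("gerp_score")), flg("in_gerp_element"),
    num(c("dnds_macaque", "dnds_mouse")),
    num(c("af_panel", paste0("af_panel_", populations), "af_esp", "af_exac",
          "pli")),
    flg(paste0("in_", domain_categories)),
    flg(paste0("ptm_", ptm_types)),
    flg(c("disordered", "mirna_site")),
    num("splice_score"),
    num(c("dist_dominant", "dist_recessive", paste0("centrality_", networks))),
    num(c(sprintf("expr_t%02d", seq_len(tissues)), "expr_entropy")),
    num("transcript_length"), flg("is_longest"),
    cat_("isoform_coverage", c("full", "partial")),
    flg(c("seg_dup", "pseudogene", "paralog")),
    num(c("syn_density", "nonsyn_density", "syn_mean_gerp", "nonsyn_mean_gerp",
          "pct_syn_in_elements", "pct_nonsyn_in_elements",
          "pct_transcript_in_elements")),
    num(c(paste0("het_syn_", ethnicities), paste0("het_nonsyn_", ethnicities)))
  )
  rownames(spec) <- NULL
  structure(spec, class = c("moi_catalogue", "data.frame"),
            tissues = tissues, populations = populations,
            ethnicities = ethnicities, ptm_types = ptm_types,
            domain_categories = domain_categories, networks = networks)
}

catalogue_names <- function(cat) cat$name

validate_catalogue <- function(cat) {
  if (!inherits(cat, "moi_catalogue"))
    stop_validation("not a feature catalogue")
  if (anyDuplicated(cat$name))
    stop_validation("duplicate feature names in catalogue")
  invisible(cat)
}
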