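## Resource tables.
##
## Every resource file is tab-delimited with a single header line and '.' for
## missing values, so fixtures stay writable by hand.  Gene identity is the
## case-sensitive symbol string.  Genomic intervals are half-open 0-based
## internally; a position is inside [start, end) iff start <= pos < end.
## Lookups for absent keys return NA, never a default value.

# ---- site tables -----------------------------------------------------------

#' Load a per-site value table
#'
#' A site table resolves (chrom, pos) -- optionally also the alternate
#' allele -- to named numeric values: per-base GERP scores, per-panel allele
#' frequencies, precomputed splice scores.  Positions are 1-based as in VCF.
#'
#' @param path tab-delimited file with a header; columns \code{chrom},
#'   \code{pos}, optionally \code{alt}, then one column per declared value.
#' @param values character vector naming the expected value columns.
#' @param af_cols subset of \code{values} validated to lie in [0, 1].
#' @return A keyed data.table of class \code{"site_table"}.
#' @export
load_site_table <- function(path, values, af_cols = character()) {
  dt <- read_tsv(path, colClasses = "character")
  need <- c("chrom", "pos", values)
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_validation("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  has_alt <- "alt" %in% names(dt)
  n <- nrow(dt)
  if (n) {
    pos <- suppressWarnings(as.numeric(dt$pos))
    bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
    if (length(bad))
      stop_validation("%s: line %d: position '%s' is not a positive integer",
                      path, bad[1] + 1L, dt$pos[bad[1]])
    dt[, "pos" := as.integer(pos)]
    for (v in values) {
      num <- suppressWarnings(as.numeric(dt[[v]]))
      bad <- which(is.na(num) & !is.na(dt[[v]]))
      if (length(bad))
        stop_validation("%s: line %d: column %s: '%s' is not numeric",
                        path, bad[1] + 1L, v, dt[[v]][bad[1]])
      dt[, (v) := num]
    }
    for (v in intersect(af_cols, values)) {
      bad <- which(!is.na(dt[[v]]) & (dt[[v]] < 0 | dt[[v]] > 1))
      if (length(bad))
        stop_validation("%s: line %d: allele frequency %s=%g outside [0,1]",
                        path, bad[1] + 1L, v, dt[[v]][bad[1]])
    }
  } else {
    dt <- data.table(chrom = character(), pos = integer())
    if (has_alt) dt[, "alt" := character()]
    for (v in values) dt[, (v) := numeric()]
  }
  key <- if (has_alt) c("chrom", "pos", "alt") else c("chrom", "pos")
  if (anyDuplicated(dt, by = key))
    stop_validation("%s: duplicate site key (one record per key required)", path)
  data.table::setkeyv(dt, key)
  structure(dt, class = c("site_table", class(dt)),
            values = values, has_alt = has_alt)
}

#' @rdname load_site_table
#' @param table a \code{site_table}.
#' @export
write_site_table <- function(table, path) {
  write_tsv(data.table::as.data.table(table), path)
}

## Vectorized lookup; rows absent from the table yield NA.
site_lookup <- function(table, chrom, pos, alt = NULL, col) {
  if (is.null(table)) return(rep(NA_real_, length(pos)))
  q <- data.table(chrom = chrom, pos = as.integer(pos))
  if (isTRUE(attr(table, "has_alt"))) {
    if (is.null(alt)) stop_contract("site table is allele-keyed; alt required")
    q[, "alt" := alt]
  }
  table[q, on = data.table::key(table)][[col]]
}

# ---- interval tracks -------------------------------------------------------

#' Load an interval track
#'
#' Interval tracks carry category-labelled half-open intervals either in
#' genomic space (\code{chrom}, \code{start}, \code{end}) or in protein
#' space (\code{transcript}, \code{start}, \code{end} in 1-based codon
#' indices).  Used for GERP elements, protein domains, PTM sites, disordered
#' regions and miRNA binding sites.
#'
#' @param path tab-delimited file with header.
#' @param space \code{"genomic"} or \code{"protein"}.
#' @param categories optional declared vocabulary; labels outside it are
#'   rejected.
#' @return data.table of class \code{"interval_track"}.
#' @export
load_interval_track <- function(path, space = c("genomic", "protein"),
                                categories = NULL) {
  space <- match.arg(space)
  dt <- read_tsv(path)
  keycol <- if (space == "genomic") "chrom" else "transcript"
  need <- c(keycol, "start", "end", "category")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_validation("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if (nrow(dt)) {
    bad <- which(!(dt$start < dt$end))
    if (length(bad))
      stop_validation("%s: line %d: empty or inverted interval [%s, %s)",
                      path, bad[1] + 1L, dt$start[bad[1]], dt$end[bad[1]])
    if (!is.null(categories)) {
      extra <- setdiff(unique(dt$category), categories)
      if (length(extra))
        stop_validation("%s: unknown categories: %s", path,
                        paste(extra, collapse = ", "))
    }
  }
  dt[, "start" := as.integer(dt$start)]
  dt[, "end" := as.integer(dt$end)]
  structure(dt, class = c("interval_track", class(dt)), space = space)
}

#' @rdname load_interval_track
#' @param track an \code{interval_track}.
#' @export
write_interval_track <- function(track, path) {
  write_tsv(data.table::as.data.table(track), path)
}

## For each (key, pos) query row, TRUE iff some interval of `category`
## contains pos under the half-open rule start <= pos < end.
track_hit <- function(track, key, pos, category = NULL) {
  if (is.null(track) || nrow(track) == 0) return(rep(FALSE, length(pos)))
  tr <- data.table::copy(data.table::as.data.table(track))
  if (!is.null(category)) {
    keep_rows <- which(tr[["category"]] %in% category)
    tr <- tr[keep_rows, ]
  }
  if (!nrow(tr)) return(rep(FALSE, length(pos)))
  keycol <- if (attr(track, "space") == "genomic") "chrom" else "transcript"
  q <- data.table(k = key, p = as.integer(pos), idx = seq_along(pos))
  data.table::setnames(tr, keycol, "k")
  hits <- tr[q, on = .(k, start <= p, end > p), nomatch = NULL,
             allow.cartesian = TRUE]
  out <- rep(FALSE, length(pos))
  out[unique(hits$idx)] <- TRUE
  out
}

# ---- gene table ------------------------------------------------------------

GENE_FLAG_COLS <- c("seg_dup", "pseudogene", "paralog")

#' Load the per-gene resource table
#'
#' One row per gene symbol: dN/dS against macaque and mouse, the pLI
#' loss-of-function constraint score, segmental-duplication / pseudogene /
#' paralog flags (0/1), one centrality column per network
#' (\code{centrality_*}) and one mean-expression column per tissue
#' (\code{expr_t*}).
#'
#' @param path tab-delimited file with header; first column \code{gene}.
#' @return keyed data.table of class \code{"gene_table"}.
#' @export
load_gene_table <- function(path) {
  dt <- read_tsv(path)
  if (!"gene" %in% names(dt))
    stop_validation("%s: missing 'gene' column", path)
  if (nrow(dt) && anyDuplicated(dt$gene))
    stop_validation("%s: duplicate gene symbols", path)
  if (nrow(dt)) {
    if ("pli" %in% names(dt)) {
      bad <- which(!is.na(dt$pli) & (dt$pli < 0 | dt$pli > 1))
      if (length(bad))
        stop_validation("%s: line %d: pli=%g outside [0,1]", path,
                        bad[1] + 1L, dt$pli[bad[1]])
    }
    for (v in intersect(c("dnds_macaque", "dnds_mouse"), names(dt))) {
      bad <- which(!is.na(dt[[v]]) & dt[[v]] < 0)
      if (length(bad))
        stop_validation("%s: line %d: %s=%g negative", path, bad[1] + 1L,
                        v, dt[[v]][bad[1]])
    }
    for (v in grep("^expr_t", names(dt), value = TRUE)) {
      bad <- which(!is.na(dt[[v]]) & dt[[v]] < 0)
      if (length(bad))
        stop_validation("%s: line %d: expression %s=%g negative", path,
                        bad[1] + 1L, v, dt[[v]][bad[1]])
    }
  }
  for (v in intersect(GENE_FLAG_COLS, names(dt)))
    dt[, (v) := as.logical(dt[[v]])]
  data.table::setkeyv(dt, "gene")
  structure(dt, class = c("gene_table", class(dt)))
}

#' @rdname load_gene_table
#' @param table a \code{gene_table}.
#' @export
write_gene_table <- function(table, path) {
  dt <- data.table::copy(data.table::as.data.table(table))
  for (v in intersect(GENE_FLAG_COLS, names(dt)))
    dt[, (v) := as.integer(dt[[v]])]
  write_tsv(dt, path)
}

# ---- gene sets -------------------------------------------------------------

#' Load named gene sets
#'
#' Curated gene lists (dominant, recessive, haploinsufficient disease
#' genes), stored as a two-column \code{set}/\code{gene} file.
#'
#' @param path tab-delimited file with header columns \code{set},
#'   \code{gene}.
#' @return named list of unique gene-symbol vectors, class
#'   \code{"gene_sets"}.
#' @export
load_gene_sets <- function(path) {
  dt <- read_tsv(path, colClasses = "character")
  miss <- setdiff(c("set", "gene"), names(dt))
  if (length(miss))
    stop_validation("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  bad <- which(is.na(dt$gene) | dt$gene == "" | is.na(dt$set) | dt$set == "")
  if (length(bad))
    stop_validation("%s: line %d: blank set or gene symbol", path, bad[1] + 1L)
  sets <- lapply(split(dt$gene, dt$set), unique)
  if (!length(sets)) stop_validation("%s: no gene sets", path)
  structure(sets, class = "gene_sets")
}

#' @rdname load_gene_sets
#' @param sets a \code{gene_sets} list.
#' @export
write_gene_sets <- function(sets, path) {
  dt <- data.table(set = rep(names(sets), lengths(sets)),
                   gene = unlist(sets, use.names = FALSE))
  write_tsv(dt, path)
}

# ---- interaction network ---------------------------------------------------

#' Load a protein-protein interaction network
#'
#' Two-column gene-symbol edge list (header line); the graph is undirected
#' and duplicate edges are collapsed.  Self-loops are permitted.
#'
#' @param path edge-list file.
#' @return an \code{igraph} undirected graph.
#' @export
load_network <- function(path) {
  dt <- read_tsv(path, colClasses = "character")
  if (ncol(dt) < 2)
    stop_validation("%s: expected two gene-symbol columns", path)
  a <- dt[[1]]; b <- dt[[2]]
  bad <- which(is.na(a) | a == "" | is.na(b) | b == "")
  if (length(bad))
    stop_validation("%s: line %d: blank gene symbol", path, bad[1] + 1L)
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

#' @rdname load_network
#' @param net an igraph network.
#' @export
write_network <- function(net, path) {
  e <- igraph::as_edgelist(net)
  write_tsv(data.table(gene1 = e[, 1], gene2 = e[, 2]), path)
}

# ---- polymorphism table ----------------------------------------------------

#' Load the per-transcript polymorphism table
#'
#' One row per known SNP: transcript id, SNP class (\code{syn} /
#' \code{nonsyn}), minor allele frequency \code{maf} (p), reference allele
#' frequency \code{ref_af} (q), GERP score, GERP-element membership flag and
#' ethnicity tag.  Drives SNP density, mean-GERP, percent-in-element and
#' per-ethnicity average-heterozygosity features.
#'
#' @param path tab-delimited file with header.
#' @return data.table of class \code{"polymorphism_table"}.
#' @export
load_polymorphism_table <- function(path) {
  dt <- read_tsv(path)
  need <- c("transcript", "snp_class", "maf", "ref_af", "gerp", "in_element",
            "ethnicity")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_validation("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if (nrow(dt)) {
    bad <- which(!dt$snp_class %in% c("syn", "nonsyn"))
    if (length(bad))
      stop_validation("%s: line %d: snp_class '%s'", path, bad[1] + 1L,
                      dt$snp_class[bad[1]])
    bad <- which(!is.na(dt$maf) & (dt$maf < 0 | dt$maf > 0.5))
    if (length(bad))
      stop_validation("%s: line %d: minor allele frequency %g outside [0,0.5]",
                      path, bad[1] + 1L, dt$maf[bad[1]])
    bad <- which(!is.na(dt$maf) & !is.na(dt$ref_af) &
                   dt$maf + dt$ref_af > 1 + 1e-6)
    if (length(bad))
      stop_validation("%s: line %d: p + q = %g exceeds 1", path, bad[1] + 1L,
                      dt$maf[bad[1]] + dt$ref_af[bad[1]])
    dt[, "in_element" := as.logical(dt$in_element)]
  }
  structure(dt, class = c("polymorphism_table", class(dt)))
}

#' @rdname load_polymorphism_table
#' @param table a \code{polymorphism_table}.
#' @export
write_polymorphism_table <- function(table, path) {
  dt <- data.table::copy(data.table::as.data.table(table))
  if (nrow(dt)) dt[, "in_element" := as.integer(dt$in_element)]
  write_tsv(dt, path)
}

# ---- bundle ----------------------------------------------------------------

RESOURCE_FILES <- c(
  gerp_sites = "gerp_sites.tsv", af_sites = "af_sites.tsv",
  splice_sites = "splice_sites.tsv", gerp_elements = "gerp_elements.tsv",
  domains = "domains.tsv", ptms = "ptms.tsv", disorder = "disorder.tsv",
  mirna_sites = "mirna_sites.tsv", gene_table = "gene_table.tsv",
  gene_sets = "gene_sets.tsv", network = "network.tsv",
  polymorphisms = "polymorphisms.tsv")

#' Bundle annotation resources
#'
#' Collects every resource object the annotation pipeline consumes.  Any
#' member may be NULL; the corresponding features are then emitted as
#' missing.
#'
#' @param gerp_sites,af_sites,splice_sites site tables.
#' @param gerp_elements,mirna_sites genomic interval tracks.
#' @param domains,ptms,disorder protein-coordinate interval tracks.
#' @param gene_table per-gene table.
#' @param gene_sets named gene sets (needs \code{dominant} and
#'   \code{recessive} for the shortest-path features).
#' @param network igraph interaction network.
#' @param polymorphisms polymorphism table.
#' @return list of class \code{"moi_resources"}.
#' @export
moi_resources <- function(gerp_sites = NULL, af_sites = NULL,
                          splice_sites = NULL, gerp_elements = NULL,
                          domains = NULL, ptms = NULL, disorder = NULL,
                          mirna_sites = NULL, gene_table = NULL,
                          gene_sets = NULL, network = NULL,
                          polymorphisms = NULL) {
  structure(list(gerp_sites = gerp_sites, af_sites = af_sites,
                 splice_sites = splice_sites, gerp_elements = gerp_elements,
                 domains = domains, ptms = ptms, disorder = disorder,
                 mirna_sites = mirna_sites, gene_table = gene_table,
                 gene_sets = gene_sets, network = network,
                 polymorphisms = polymorphisms),
            class = "moi_resources")
}

#' Read or write a full resource directory
#'
#' Standard file names are used for each resource (see
#' \code{varmoi:::RESOURCE_FILES}); absent files load as NULL.
#'
#' @param dir directory of resource files.
#' @param catalogue feature catalogue (declares AF columns and category
#'   vocabularies).
#' @return \code{load_resources}: an \code{moi_resources} bundle.
#' @export
load_resources <- function(dir, catalogue = default_catalogue()) {
  p <- function(nm) file.path(dir, RESOURCE_FILES[[nm]])
  have <- function(nm) file.exists(p(nm))
  pops <- attr(catalogue, "populations")
  af_cols <- c("af_panel", paste0("af_panel_", pops), "af_esp", "af_exac")
  moi_resources(
    gerp_sites = if (have("gerp_sites"))
      load_site_table(p("gerp_sites"), values = "gerp"),
    af_sites = if (have("af_sites"))
      load_site_table(p("af_sites"), values = af_cols, af_cols = af_cols),
    splice_sites = if (have("splice_sites"))
      load_site_table(p("splice_sites"), values = "splice_score"),
    gerp_elements = if (have("gerp_elements"))
      load_interval_track(p("gerp_elements"), "genomic"),
    domains = if (have("domains"))
      load_interval_track(p("domains"), "protein",
                          categories = attr(catalogue, "domain_categories")),
    ptms = if (have("ptms"))
      load_interval_track(p("ptms"), "protein",
                          categories = attr(catalogue, "ptm_types")),
    disorder = if (have("disorder"))
      load_interval_track(p("disorder"), "protein", categories = "disordered"),
    mirna_sites = if (have("mirna_sites"))
      load_interval_track(p("mirna_sites"), "genomic", categories = "mirna"),
    gene_table = if (have("gene_table")) load_gene_table(p("gene_table")),
    gene_sets = if (have("gene_sets")) load_gene_sets(p("gene_sets")),
    network = if (have("network")) load_network(p("network")),
    polymorphisms = if (have("polymorphisms"))
      load_polymorphism_table(p("polymorphisms")))
}

#' @rdname load_resources
#' @param resources an \code{moi_resources} bundle.
#' @export
write_resources <- function(resources, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(nm) file.path(dir, RESOURCE_FILES[[nm]])
  w <- function(obj, nm, fun) if (!is.null(obj)) fun(obj, p(nm))
  w(resources$gerp_sites, "gerp_sites", write_site_table)
  w(resources$af_sites, "af_sites", write_site_table)
  w(resources$splice_sites, "splice_sites", write_site_table)
  w(resources$gerp_elements, "gerp_elements", write_interval_track)
  w(resources$domains, "domains", write_interval_track)
  w(resources$ptms, "ptms", write_interval_track)
  w(resources$disorder, "disorder", write_interval_track)
  w(resources$mirna_sites, "mirna_sites", write_interval_track)
  w(resources$gene_table, "gene_table", write_gene_table)
  w(resources$gene_sets, "gene_sets", write_gene_sets)
  w(resources$network, "network", write_network)
  w(resources$polymorphisms, "polymorphisms", write_polymorphism_table)
  invisible(dir)
}
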