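## Synthetic fixtures: toy genome + transcript models, class-labelled
## variant pools and a full resource-table set with tunable
## class-conditional feature distributions.
##
## One global seed drives every component through a documented derivation
## (reference: offset 1, pools: offset 2, resources: offset 3), so
## components can be regenerated independently and identical seeds yield
## byte-identical files.

#' Fixture configuration
#'
#' Defaults mirror the structure of the training data the classifier was
#' designed for: 292 benign, 119 dominant (haploinsufficient) and 409
#' recessive genes carrying 1024, 598 and 2413 variants respectively, 25
#' tissues, and a class separation \code{delta} large enough that the
#' three classes are strongly distinguishable (the regime the method
#' operates in on real curated data).  \code{delta} scales the shift
#' applied to the class means of the signal features (GERP, allele
#' frequencies, dN/dS, pLI, disease-gene-set membership); at
#' \code{delta = 0} all class-conditional distributions are identical.
#'
#' @param genes_per_class named counts of genes per class.
#' @param variants_per_class named total pool sizes per class.
#' @param delta class-separation shift (>= 0).
#' @param n_signal,n_noise signal/noise feature counts for
#'   \code{\link{simulate_feature_matrix}}.
#' @param missingness named per-family missingness rates (entries
#'   \code{gerp}, \code{af}, \code{splice}, \code{gene}), each in [0, 1].
#' @param tissues number of expression tissues.
#' @param n_chroms chromosomes in the toy genome.
#' @param cds_codons min/max codons per primary CDS.
#' @param exons_per_gene min/max CDS exons per gene.
#' @param second_isoform_rate fraction of genes given a second, shorter
#'   isoform.
#' @return list of class \code{"fixture_config"}.
#' @export
fixture_config <- function(genes_per_class = c(benign = 292, dominant = 119,
                                               recessive = 409),
                           variants_per_class = c(benign = 1024,
                                                  dominant = 598,
                                                  recessive = 2413),
                           delta = 3,
                           n_signal = 5, n_noise = 20,
                           missingness = c(gerp = 0.1, af = 0.1,
                                           splice = 0.7, gene = 0.05),
                           tissues = 25, n_chroms = 4,
                           cds_codons = c(60, 200),
                           exons_per_gene = c(1, 4),
                           second_isoform_rate = 0.2) {
  if (delta < 0) stop_validation("delta must be >= 0")
  if (any(missingness < 0 | missingness > 1))
    stop_validation("missingness rates must lie in [0, 1]")
  if (any(genes_per_class < 1) || any(variants_per_class < 1) ||
      tissues < 1 || n_signal < 1 || n_noise < 0)
    stop_validation("counts must be positive")
  if (any(variants_per_class < genes_per_class[names(variants_per_class)]))
    stop_validation("each gene needs at least one variant")
  structure(list(genes_per_class = genes_per_class,
                 variants_per_class = variants_per_class, delta = delta,
                 n_signal = n_signal, n_noise = n_noise,
                 missingness = missingness, tissues = tissues,
                 n_chroms = n_chroms, cds_codons = cds_codons,
                 exons_per_gene = exons_per_gene,
                 second_isoform_rate = second_isoform_rate),
            class = "fixture_config")
}

## Class-mean offsets (scaled by delta) for the signal feature families;
## chosen so benign/pathogenic separate on constraint and frequency while
## dominant/recessive separate mainly on pLI and disease-set membership.
SIGNAL_OFFSETS <- list(
  gerp = c(benign = 0, dominant = 1, recessive = 0.8),
  af = c(benign = 0, dominant = 1.2, recessive = 0.9),
  dnds = c(benign = 0, dominant = 0.5, recessive = 0.35),
  pli = c(benign = 0, dominant = 1.5, recessive = 0.3),
  set_dom = c(benign = 0, dominant = 1.2, recessive = 0),
  set_rec = c(benign = 0, dominant = 0, recessive = 1.2))

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  all <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  ok <- setdiff(all, STOP_CODONS)
  sample(ok, n, replace = TRUE)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a toy reference genome and transcript models
#'
#' Random multi-exon genes on both strands: each primary CDS starts with
#' ATG, ends with a stop codon, contains no internal stop and has length
#' divisible by 3.  A fraction of genes gets a second, shorter isoform
#' (a 5' subset of the primary CDS truncated at a codon boundary).
#' Deterministic per seed.
#'
#' @param config a \code{\link{fixture_config}}.
#' @param seed global fixture seed.
#' @return \code{moi_reference} with a \code{genes} table carrying the
#'   class assignment of each gene.
#' @export
generate_reference <- function(config = fixture_config(), seed = 1) {
  with_seed(derive_seed(seed, 1L), {
    gpc <- config$genes_per_class
    genes <- data.table(
      gene = unlist(lapply(names(gpc), function(cl)
        sprintf("G%s%04d", toupper(substr(cl, 1, 1)), seq_len(gpc[[cl]])))),
      class = rep(names(gpc), gpc))
    n <- nrow(genes)
    genes[, "chrom" := sprintf("chr%d", (seq_len(n) - 1L) %% config$n_chroms + 1L)]
    genes[, "strand" := sample(c("+", "-"), n, replace = TRUE)]
    exon_rows <- list()
    chrom_parts <- stats::setNames(vector("list", config$n_chroms),
                                   sprintf("chr%d", seq_len(config$n_chroms)))
    cursor <- stats::setNames(rep(0L, config$n_chroms), names(chrom_parts))
    for (i in seq_len(n)) {
      g <- genes$gene[i]; chrom <- genes$chrom[i]; strand <- genes$strand[i]
      n_cod <- sample(config$cds_codons[1]:config$cds_codons[2], 1)
      cds <- paste0("ATG", paste(random_codons(n_cod - 2L), collapse = ""),
                    sample(STOP_CODONS, 1))
      L <- nchar(cds)
      k <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      cuts <- if (k > 1) sort(sample(seq_len(L - 1L), k - 1L)) else integer()
      starts <- c(1L, cuts + 1L); ends <- c(cuts, L)
      chunks <- substring(cds, starts, ends)   # CDS order 5'->3'
      introns <- if (k > 1) sample(20:100, k - 1L, replace = TRUE) else integer()
      gap <- sample(200:500, 1)
      ## left-to-right genomic chunk order
      ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      pos <- cursor[[chrom]] + gap
      parts <- list(paste(sample(BASES, gap, replace = TRUE), collapse = ""))
      for (j in seq_len(k)) {
        chunk <- chunks[ord[j]]
        seq_j <- if (strand == "+") chunk else revcomp(chunk)
        len <- nchar(chunk)
        exon_rows[[length(exon_rows) + 1L]] <- data.table(
          transcript = paste0(g, ".t1"), gene = g, chrom = chrom,
          strand = strand, start = pos, end = pos + len,
          cds_chunk = ord[j])
        parts[[length(parts) + 1L]] <- seq_j
        pos <- pos + len
        if (j < k) {
          il <- introns[j]
          parts[[length(parts) + 1L]] <-
            paste(sample(BASES, il, replace = TRUE), collapse = "")
          pos <- pos + il
        }
      }
      chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], parts)
      cursor[[chrom]] <- pos
      ## optional shorter second isoform: 5' exon subset, codon-trimmed
      if (k > 1 && stats::runif(1) < config$second_isoform_rate) {
        ex_g <- data.table::rbindlist(tail(exon_rows, k))
        data.table::setorder(ex_g, cds_chunk)
        keep <- seq_len(max(1L, k %/% 2L))
        ex2 <- ex_g[keep, ]
        L2 <- sum(ex2$end - ex2$start)
        trim <- L2 %% 3L
        last <- nrow(ex2)
        if (L2 - trim >= 6L && ex2$end[last] - ex2$start[last] > trim) {
          if (strand == "+") ex2$end[last] <- ex2$end[last] - trim
          else ex2$start[last] <- ex2$start[last] + trim
          ex2[, "transcript" := paste0(g, ".t2")]
          exon_rows[[length(exon_rows) + 1L]] <- ex2
        }
      }
    }
    genome <- vapply(chrom_parts, paste, character(1), collapse = "")
    ex <- data.table::rbindlist(exon_rows)
    ex[, "cds_chunk" := NULL]
    moi_reference(genome, transcript_models(ex), genes = genes)
  })
}

## cds index split per transcript: list(gpos ordered 5'->3', seq)
per_transcript_maps <- function(cds) {
  idx <- cds$index[order(cds$index$transcript, cds$index$cds_pos), ]
  list(gpos = split(idx$gpos, idx$transcript),
       chrom = split(idx$chrom, idx$transcript),
       seqs = cds$seqs)
}

#' Generate class-labelled variant pools
#'
#' For each class, distributes the configured pool size over the class's
#' genes and draws genuine nonsynonymous substitutions against each
#' gene's primary transcript (internal codons only; substitutions
#' creating or destroying stop codons are excluded).
#'
#' @param ref \code{moi_reference} from \code{\link{generate_reference}}.
#' @param config a \code{\link{fixture_config}}.
#' @param seed global fixture seed.
#' @return data.table of class \code{"moi_pools"}: chrom, pos, ref, alt,
#'   gene, class.
#' @export
generate_labeled_pools <- function(ref, config = fixture_config(), seed = 1) {
  cds <- build_cds_index(ref)
  maps <- per_transcript_maps(cds)
  code <- Biostrings::GENETIC_CODE
  with_seed(derive_seed(seed, 2L), {
    rows <- list()
    for (cl in names(config$genes_per_class)) {
      gg <- ref$genes[ref$genes$class == cl, ]
      ng <- nrow(gg)
      total <- config$variants_per_class[[cl]]
      counts <- rep(total %/% ng, ng)
      extra <- total %% ng
      if (extra) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
      for (i in seq_len(ng)) {
        g <- gg$gene[i]; tx <- paste0(g, ".t1")
        seq_t <- maps$seqs[[tx]]
        gpos <- maps$gpos[[tx]]
        strand <- gg$strand[i]
        n_cod <- nchar(seq_t) %/% 3L
        m <- counts[i]
        codons <- sample(2:(n_cod - 1L), min(m, n_cod - 2L))
        for (ci in codons) {
          codon <- substr(seq_t, 3L * ci - 2L, 3L * ci)
          subs <- expand.grid(off = 1:3, alt = BASES,
                              stringsAsFactors = FALSE)
          subs <- subs[sample.int(nrow(subs)), ]
          for (s in seq_len(nrow(subs))) {
            off <- subs$off[s]; alt_cds <- subs$alt[s]
            if (substr(codon, off, off) == alt_cds) next
            alt_codon <- codon
            substr(alt_codon, off, off) <- alt_cds
            aa0 <- code[[codon]]; aa1 <- code[[alt_codon]]
            if (aa0 != aa1 && aa1 != "*" && aa0 != "*") {
              cpos <- 3L * (ci - 1L) + off
              gp <- gpos[cpos]
              ref_cds <- substr(codon, off, off)
              ref_g <- if (strand == "+") ref_cds else
                chartr("ACGT", "TGCA", ref_cds)
              alt_g <- if (strand == "+") alt_cds else
                chartr("ACGT", "TGCA", alt_cds)
              rows[[length(rows) + 1L]] <- data.table(
                chrom = gg$chrom[i], pos = gp, ref = ref_g, alt = alt_g,
                gene = g, class = cl)
              break
            }
          }
        }
      }
    }
    pools <- data.table::rbindlist(rows)
    structure(pools, class = c("moi_pools", class(pools)))
  })
}

#' Write / read variant pools (VCF + label file)
#'
#' @param pools \code{moi_pools} table.
#' @param dir output directory; writes \code{pools.vcf} and
#'   \code{labels.tsv}.
#' @export
write_pools <- function(pools, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(pools, file.path(dir, "pools.vcf"))
  write_tsv(data.table::as.data.table(pools), file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @rdname write_pools
#' @export
read_pools <- function(dir) {
  dt <- read_tsv(file.path(dir, "labels.tsv"),
                 colClasses = list(character = c("chrom", "ref", "alt",
                                                 "gene", "class")))
  dt[, "pos" := as.integer(dt$pos)]
  structure(dt, class = c("moi_pools", class(dt)))
}

#' Generate the full synthetic resource-table set
#'
#' Site tables are keyed on the supplied variant sites (plus background
#' polymorphism sites); gene-level values, gene sets, the interaction
#' network, tracks and the polymorphism table cover all genes.
#' Class-linked features (GERP, allele frequencies, dN/dS, pLI,
#' disease-set membership, nonsynonymous SNP load) are drawn from
#' class-shifted distributions scaled by \code{config$delta}; all other
#' families are class-independent noise.  Missingness is injected by
#' withholding table entries at the configured per-family rates.
#'
#' @param ref \code{moi_reference}.
#' @param config a \code{\link{fixture_config}}.
#' @param seed global fixture seed.
#' @param variants optional \code{moi_pools}/variant table whose sites
#'   the site tables must cover; defaults to a per-gene sample of coding
#'   positions.
#' @return an \code{moi_resources} bundle.
#' @export
generate_resources <- function(ref, config = fixture_config(), seed = 1,
                               variants = NULL) {
  delta <- config$delta
  miss <- config$missingness
  genes <- ref$genes
  tx <- ref$models$tx
  cds <- build_cds_index(ref)
  with_seed(derive_seed(seed, 3L), {
    if (is.null(variants)) {
      idx <- cds$index
      take <- idx[, .SD[sample.int(.N, min(20L, .N))], by = "transcript"]
      m <- match(take$transcript, tx$transcript)
      variants <- data.table(chrom = take$chrom, pos = take$gpos,
                             alt = sample(BASES, nrow(take), replace = TRUE),
                             gene = tx$gene[m])
    }
    v <- unique(data.table::as.data.table(variants),
                by = c("chrom", "pos", "alt"))
    vclass <- genes$class[match(v$gene, genes$gene)]
    nv <- nrow(v)

    ## per-site GERP, keyed (chrom, pos)
    vs <- unique(v[, c("chrom", "pos"), with = FALSE])
    sclass <- vclass[match(paste(vs$chrom, vs$pos), paste(v$chrom, v$pos))]
    gerp <- data.table(chrom = vs$chrom, pos = vs$pos,
                       gerp = rnorm(nrow(vs),
                                    delta * SIGNAL_OFFSETS$gerp[sclass], 1))
    keep_g <- runif(nrow(gerp)) >= miss[["gerp"]]
    gerp_sites <- as_site_table(gerp[keep_g, ], values = "gerp")

    ## allele frequencies, keyed (chrom, pos, alt)
    af0 <- pmin(exp(rnorm(nv, log(0.05) - delta * SIGNAL_OFFSETS$af[vclass],
                          0.8)), 0.5)
    af <- data.table(chrom = v$chrom, pos = v$pos, alt = v$alt,
                     af_panel = af0)
    for (pop in c("afr", "eur", "eas"))
      af[, (paste0("af_panel_", pop)) :=
           pmin(af0 * runif(nv, 0.5, 1.5), 1)]
    af[, "af_esp" := pmin(af0 * runif(nv, 0.6, 1.4), 1)]
    af[, "af_exac" := pmin(af0 * runif(nv, 0.6, 1.4), 1)]
    keep_a <- runif(nrow(af)) >= miss[["af"]]
    af <- af[keep_a, ]
    af_cols <- setdiff(names(af), c("chrom", "pos", "alt"))
    af_sites <- as_site_table(af, values = af_cols, af_cols = af_cols)

    ## sparse splice scores (noise)
    keep_s <- runif(nrow(vs)) >= miss[["splice"]]
    sp <- vs[keep_s, ]
    splice_sites <- as_site_table(
      data.table(chrom = sp$chrom, pos = sp$pos,
                 splice_score = rnorm(nrow(sp))), values = "splice_score")

    ## GERP elements: random subintervals of exons, mildly deeper coverage
    ## for constrained (pathogenic-class) genes
    ex <- ref$models$exons
    exg <- genes$class[match(ex$gene, genes$gene)]
    pcov <- 0.3 + 0.05 * delta * (exg != "benign")
    keep <- runif(nrow(ex)) < pcov
    eks <- ex[keep, ]
    s <- eks$start + floor(runif(nrow(eks)) * pmax(eks$end - eks$start - 3L, 1L))
    e <- pmin(s + 3L + floor(runif(nrow(eks)) * 40L), eks$end)
    gerp_elements <- structure(
      data.table(chrom = eks$chrom, start = as.integer(s),
                 end = as.integer(e), category = "gerp_element")[s < e, ],
      class = c("interval_track", "data.table", "data.frame"),
      space = "genomic")

    ## protein-coordinate tracks (class-blind noise)
    prot_track <- function(categories, prob, space_len = c(5L, 30L)) {
      rows <- list()
      for (cat in categories) {
        sel <- runif(nrow(tx)) < prob
        if (!any(sel)) next
        tt <- tx[sel, ]
        plen <- tt$cds_length %/% 3L
        st <- pmax(1L, floor(runif(nrow(tt)) * pmax(plen - space_len[1], 1L)))
        en <- pmin(st + space_len[1] +
                     floor(runif(nrow(tt)) * diff(space_len)), plen + 1L)
        rows[[cat]] <- data.table(transcript = tt$transcript,
                                  start = as.integer(st),
                                  end = as.integer(en), category = cat)
      }
      dt <- data.table::rbindlist(rows)
      dt <- dt[dt$start < dt$end, ]
      structure(dt, class = c("interval_track", "data.table", "data.frame"),
                space = "protein")
    }
    domains <- prot_track(c("pfam", "smart", "scop", "signal_peptide",
                            "transmembrane"), 0.4)
    ptms <- prot_track(c("phosphorylation", "methylation", "acetylation",
                         "ubiquitination"), 0.3, c(1L, 4L))
    disorder <- prot_track("disordered", 0.3, c(10L, 40L))

    ## sparse genomic miRNA-site track
    mi_sel <- runif(nrow(ex)) < 0.05
    mie <- ex[mi_sel, ]
    mirna_sites <- structure(
      data.table(chrom = mie$chrom, start = mie$start,
                 end = pmin(mie$start + 8L, mie$end), category = "mirna"),
      class = c("interval_track", "data.table", "data.frame"),
      space = "genomic")

    ## gene table
    ng <- nrow(genes)
    cls <- genes$class
    gt <- data.table(gene = genes$gene)
    gt[, "dnds_macaque" := exp(rnorm(ng, log(0.4) -
                                       delta * SIGNAL_OFFSETS$dnds[cls], 0.4))]
    gt[, "dnds_mouse" := exp(rnorm(ng, log(0.35) -
                                     delta * SIGNAL_OFFSETS$dnds[cls], 0.4))]
    gt[, "pli" := plogis(rnorm(ng, qlogis(0.2) +
                                 delta * SIGNAL_OFFSETS$pli[cls], 1))]
    gt[, "seg_dup" := runif(ng) < 0.15]
    gt[, "pseudogene" := runif(ng) < 0.10]
    gt[, "paralog" := runif(ng) < 0.30]
    for (nw in c("metabolic", "genetic", "signaling"))
      gt[, (paste0("centrality_", nw)) := rlnorm(ng, 0, 1)]
    for (t in seq_len(config$tissues))
      gt[, (sprintf("expr_t%02d", t)) := rlnorm(ng, 0, 1)]
    for (col in c("dnds_macaque", "dnds_mouse", "pli")) {
      na <- runif(ng) < miss[["gene"]]
      if (any(na)) gt[na, (col) := NA_real_]
    }
    data.table::setkeyv(gt, "gene")
    gene_table <- structure(gt, class = c("gene_table", "data.table",
                                          "data.frame"))

    ## disease gene sets: membership probability class-biased via delta
    p_dom <- plogis(qlogis(0.08) + delta * SIGNAL_OFFSETS$set_dom[cls])
    p_rec <- plogis(qlogis(0.08) + delta * SIGNAL_OFFSETS$set_rec[cls])
    dom <- genes$gene[runif(ng) < p_dom]
    rec <- genes$gene[runif(ng) < p_rec]
    if (!length(dom)) dom <- genes$gene[which.max(p_dom)]
    if (!length(rec)) rec <- genes$gene[which.max(p_rec)]
    hapl <- dom[runif(length(dom)) < 0.7]
    if (!length(hapl)) hapl <- dom[1]
    gene_sets <- structure(list(dominant = dom, recessive = rec,
                                haploinsufficient = hapl),
                           class = "gene_sets")

    ## interaction network: shuffled ring backbone + random extra edges
    ordg <- sample(genes$gene)
    ring <- data.frame(from = ordg, to = c(ordg[-1], ordg[1]))
    extra <- data.frame(from = sample(genes$gene, 2L * ng, replace = TRUE),
                        to = sample(genes$gene, 2L * ng, replace = TRUE))
    extra <- extra[extra$from != extra$to, ]
    network <- igraph::simplify(
      igraph::graph_from_data_frame(rbind(ring, extra), directed = FALSE),
      remove.multiple = TRUE, remove.loops = FALSE)

    ## polymorphism table: nonsynonymous SNP load depleted in constrained
    ## (pathogenic-class) genes
    prows <- list()
    tcls <- genes$class[match(tx$gene, genes$gene)]
    ## at least one SNP of each class per transcript so the density and
    ## heterozygosity aggregates are always defined
    n_syn <- pmax(1L, rpois(nrow(tx), tx$cds_length * 0.012))
    n_non <- pmax(1L, rpois(nrow(tx), tx$cds_length * 0.01 *
                              exp(-0.25 * delta * (tcls != "benign"))))
    for (cl2 in c("syn", "nonsyn")) {
      nn <- if (cl2 == "syn") n_syn else n_non
      tot <- sum(nn)
      if (!tot) next
      tr <- rep(tx$transcript, nn)
      tcl <- rep(tcls, nn)
      maf <- pmin(stats::rbeta(tot, 0.5, 8), 0.5)
      prows[[cl2]] <- data.table(
        transcript = tr, snp_class = cl2, maf = maf, ref_af = 1 - maf,
        gerp = rnorm(tot, 0.5 * delta * SIGNAL_OFFSETS$gerp[tcl], 1),
        in_element = runif(tot) < 0.3,
        ethnicity = sample(c("afr", "eur", "eas"), tot, replace = TRUE))
    }
    polymorphisms <- structure(data.table::rbindlist(prows),
                               class = c("polymorphism_table", "data.table",
                                         "data.frame"))

    moi_resources(gerp_sites = gerp_sites, af_sites = af_sites,
                  splice_sites = splice_sites, gerp_elements = gerp_elements,
                  domains = domains, ptms = ptms, disorder = disorder,
                  mirna_sites = mirna_sites, gene_table = gene_table,
                  gene_sets = gene_sets, network = network,
                  polymorphisms = polymorphisms)
  })
}

## In-memory site-table constructor (same invariants as the loader).
as_site_table <- function(dt, values, af_cols = character()) {
  has_alt <- "alt" %in% names(dt)
  key <- if (has_alt) c("chrom", "pos", "alt") else c("chrom", "pos")
  dt <- unique(dt, by = key)
  dt[, "pos" := as.integer(dt$pos)]
  data.table::setkeyv(dt, key)
  structure(dt, class = c("site_table", "data.table", "data.frame"),
            values = values, has_alt = has_alt)
}

#' Generate a complete fixture set
#'
#' Orchestrates \code{\link{generate_reference}},
#' \code{\link{generate_labeled_pools}} and
#' \code{\link{generate_resources}} under one global seed and optionally
#' writes every file (FASTA, GTF, VCF + labels, resource tables) to a
#' directory.
#'
#' @param config a \code{\link{fixture_config}}.
#' @param seed global fixture seed.
#' @param dir optional output directory.
#' @return list with \code{reference}, \code{pools}, \code{resources},
#'   \code{config}.
#' @export
simulate_fixtures <- function(config = fixture_config(), seed = 1,
                              dir = NULL) {
  ref <- generate_reference(config, seed)
  pools <- generate_labeled_pools(ref, config, seed)
  resources <- generate_resources(ref, config, seed, variants = pools)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(ref, dir)
    write_pools(pools, dir)
    write_resources(resources, file.path(dir, "resources"))
  }
  list(reference = ref, pools = pools, resources = resources,
       config = config)
}

#' Simulate an encoded feature matrix directly
#'
#' A feature-space fixture that skips the genomic pipeline: \code{n_signal}
#' features whose class means are shifted by \code{delta} times a fixed
#' per-feature class pattern (patterns alternate which class pair they
#' separate), plus \code{n_noise} independent standard-normal features.
#' Unit noise throughout; one synthetic gene per row.
#'
#' @param n_per_class named row counts per class.
#' @param n_signal,n_noise feature counts.
#' @param delta class-separation shift.
#' @param seed RNG seed.
#' @return an \code{moi_matrix} with labels (already numeric; no encoding
#'   or imputation needed).
#' @export
simulate_feature_matrix <- function(n_per_class = c(benign = 300,
                                                    dominant = 300,
                                                    recessive = 300),
                                    n_signal = 5, n_noise = 20, delta = 1,
                                    seed = 1) {
  patterns <- list(c(benign = 0, dominant = 1, recessive = 0.5),
                   c(benign = 0, dominant = 0.5, recessive = 1),
                   c(benign = 0, dominant = 1, recessive = 1),
                   c(benign = 0, dominant = 1, recessive = -0.5),
                   c(benign = 0, dominant = -0.5, recessive = 1))
  with_seed(seed, {
    labels <- factor(rep(MOI_CLASSES, n_per_class[MOI_CLASSES]),
                     levels = MOI_CLASSES)
    n <- length(labels)
    cols <- list()
    for (j in seq_len(n_signal)) {
      pat <- patterns[[(j - 1L) %% length(patterns) + 1L]]
      cols[[sprintf("signal%02d", j)]] <-
        rnorm(n, delta * pat[as.character(labels)], 1)
    }
    for (j in seq_len(n_noise))
      cols[[sprintf("noise%02d", j)]] <- rnorm(n)
    x <- do.call(cbind, cols)
    cat_df <- data.frame(name = colnames(x), type = "numeric",
                         levels = NA_character_)
    catalogue <- structure(cat_df, class = c("moi_catalogue", "data.frame"))
    ids <- data.frame(row_id = sprintf("v%05d", seq_len(n)),
                      gene = sprintf("g%05d", seq_len(n)))
    structure(list(x = x, ids = ids, labels = labels, catalogue = catalogue,
                   encoding = list(), fills = NULL),
              class = "moi_matrix")
  })
}
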