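#' Promoter proximity, 3D contacts and expression linkage
#'
#' Enhancers act on genes either from the promoter neighbourhood (within
#' 5 kb) or across larger genomic distances through 3D chromatin contacts.
#' This module classifies called regions into proximal / distal-only /
#' proximal-only / neither with respect to gene promoters (250 bp upstream
#' of the TSS) and enriched contact records (observed/expected ratio), and
#' attaches the expression of contacted genes (maximum FPKM when several
#' promoters are contacted).
#'
#' @name contacts-expression
NULL

#' Promoter intervals (250 bp upstream of the TSS, strand-aware)
#'
#' @param genes `GRanges` of gene spans with strand (`+`/`-`); the TSS is
#'   the 5' end. A `gene_id` is taken from the `ID` (or `gene_id`) column.
#' @param chrom_sizes Named lengths used for clipping; defaults to
#'   `seqlengths(genes)`.
#' @param width Promoter width (bp).
#' @return `GRanges` of promoters with a `gene_id` column.
#' @export
promoter_intervals <- function(genes, chrom_sizes = NULL, width = 250) {
  stopifnot(methods::is(genes, "GRanges"))
  if (is.null(chrom_sizes)) chrom_sizes <- GenomeInfoDb::seqlengths(genes)
  str <- as.character(GenomicRanges::strand(genes))
  if (any(!str %in% c("+", "-")))
    .stopf("gene strand must be '+' or '-'")
  lens <- chrom_sizes[as.character(GenomeInfoDb::seqnames(genes))]
  tss <- ifelse(str == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  if (any(is.na(lens)) || any(tss < 1 | tss > lens))
    .stopf("TSS outside its chromosome")
  p_start <- ifelse(str == "+", pmax(tss - width, 1L), pmin(tss + 1L, lens))
  p_end <- ifelse(str == "+", tss - 1L, pmin(tss + width, lens))
  # a TSS at the very chromosome start leaves no upstream room: clip to an
  # empty-but-valid 1 bp stub at the edge
  bad <- p_end < p_start
  p_end[bad] <- p_start[bad]
  ids <- if (!is.null(genes$ID)) genes$ID else
         if (!is.null(genes$gene_id)) genes$gene_id else
         sprintf("gene%04d", seq_along(genes))
  out <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(genes)),
    IRanges::IRanges(p_start, p_end), strand = str, gene_id = ids)
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genes)
  suppressWarnings(GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(genes))
  out
}

#' Flag enriched contact records
#'
#' @param contacts A `contact_records` data frame ([read_contacts()]).
#' @param ratio_threshold Observed/expected ratio at or above which a
#'   contact is enriched (default 2; the upstream contact caller's cutoff
#'   is deliberately explicit here).
#' @return The records with a logical `enriched` column.
#' @export
flag_enriched_contacts <- function(contacts, ratio_threshold = 2) {
  if (any(contacts$score <= 0))
    .stopf("observed/expected ratios must be positive")
  contacts$enriched <- contacts$score >= ratio_threshold
  contacts
}

.contact_anchors <- function(contacts) {
  list(a1 = GenomicRanges::GRanges(contacts$chrom1,
         IRanges::IRanges(contacts$start1, contacts$end1)),
       a2 = GenomicRanges::GRanges(contacts$chrom2,
         IRanges::IRanges(contacts$start2, contacts$end2)))
}

#' Classify regions by promoter proximity and 3D contacts
#'
#' Distance is the gap between region and nearest promoter (0 when
#' overlapping). A region "contacts" a promoter when region and promoter
#' fall in the two anchors of one enriched record; the contact is distal
#' when that promoter is more than `proximal_distance` away. Categories:
#' \describe{
#'   \item{proximal}{within 5 kb of a promoter AND has distal enriched
#'     promoter contacts}
#'   \item{proximal_only}{within 5 kb, no distal enriched contacts}
#'   \item{distal_only}{further than 5 kb from every promoter, with at
#'     least one enriched promoter contact}
#'   \item{neither}{further than 5 kb, no promoter contacts}
#' }
#'
#' @param regions `GRanges` of called regions.
#' @param promoters Output of [promoter_intervals()].
#' @param contacts Contact records with an `enriched` flag (only enriched
#'   records are used; an unflagged table counts every record).
#' @param proximal_distance Proximity cutoff in bp (default 5000).
#' @return Data frame: `region_id`, `category`, `n_contacted_genes`,
#'   `contacted_genes`, `proximal_genes`, `promoter_distance`.
#' @export
link_enhancers_to_promoters <- function(regions, promoters, contacts,
                                        proximal_distance = 5000) {
  n <- length(regions)
  region_id <- if (!is.null(names(regions)) && all(nzchar(names(regions))))
    names(regions) else sprintf("region%05d", seq_len(n))
  if ("enriched" %in% names(contacts))
    contacts <- contacts[contacts$enriched, , drop = FALSE]

  hits <- GenomicRanges::distanceToNearest(regions, promoters)
  dist <- rep(Inf, n)
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  is_prox <- dist <= proximal_distance

  # genes within the proximity cutoff (for proximal expression linkage)
  near <- GenomicRanges::findOverlaps(regions, promoters,
                                      maxgap = proximal_distance)
  prox_genes <- split(promoters$gene_id[S4Vectors::subjectHits(near)],
                      factor(S4Vectors::queryHits(near), levels = seq_len(n)))

  contacted <- vector("list", n)
  has_distal <- logical(n)
  if (nrow(contacts)) {
    an <- .contact_anchors(contacts)
    pair_up <- function(region_anchor, promoter_anchor) {
      ra <- GenomicRanges::findOverlaps(regions, region_anchor)
      pa <- GenomicRanges::findOverlaps(promoters, promoter_anchor)
      r_dt <- data.table::data.table(
        rec = S4Vectors::subjectHits(ra), region = S4Vectors::queryHits(ra))
      p_dt <- data.table::data.table(
        rec = S4Vectors::subjectHits(pa), gene = S4Vectors::queryHits(pa))
      merge(r_dt, p_dt, by = "rec", allow.cartesian = TRUE)
    }
    pairs <- rbind(pair_up(an$a1, an$a2), pair_up(an$a2, an$a1))
    if (nrow(pairs)) {
      pairs <- unique(pairs[, c("region", "gene")])
      pd <- GenomicRanges::distance(regions[pairs$region],
                                    promoters[pairs$gene])
      pd[is.na(pd)] <- Inf
      pairs$distal <- pd > proximal_distance
      for (i in unique(pairs$region)) {
        sel <- pairs$region == i
        contacted[[i]] <- unique(promoters$gene_id[pairs$gene[sel]])
        has_distal[i] <- any(pairs$distal[sel])
      }
    }
  }

  has_contact <- lengths(contacted) > 0L
  category <- ifelse(is_prox & has_distal, "proximal",
              ifelse(is_prox, "proximal_only",
              ifelse(has_contact, "distal_only", "neither")))
  data.frame(
    region_id = region_id,
    category = category,
    n_contacted_genes = lengths(contacted),
    contacted_genes = vapply(contacted, function(g)
      paste(g, collapse = ","), character(1)),
    proximal_genes = vapply(prox_genes, function(g)
      paste(unique(g), collapse = ","), character(1)),
    promoter_distance = dist,
    stringsAsFactors = FALSE)
}

#' Expression linked to each region
#'
#' The linked value is the maximum FPKM over the genes whose promoters the
#' region contacts plus, for proximal regions, the genes within the
#' proximity cutoff; `neither` regions have no defined value (NA).
#'
#' @param linkages Output of [link_enhancers_to_promoters()].
#' @param fpkm Data frame `gene_id`, `fpkm` covering every linked gene.
#' @param threshold A gene (hence region) counts as expressed when the
#'   linked FPKM strictly exceeds this (default 1).
#' @return `linkages` with `max_fpkm` and `expressed` columns.
#' @export
linked_expression <- function(linkages, fpkm, threshold = 1) {
  lookup <- setNames(fpkm$fpkm, fpkm$gene_id)
  gene_list <- function(s) if (nzchar(s)) strsplit(s, ",")[[1]] else character(0)
  vals <- vapply(seq_len(nrow(linkages)), function(i) {
    genes <- gene_list(linkages$contacted_genes[i])
    if (linkages$category[i] %in% c("proximal", "proximal_only"))
      genes <- union(genes, gene_list(linkages$proximal_genes[i]))
    if (!length(genes)) return(NA_real_)
    if (!all(genes %in% names(lookup)))
      .stopf("FPKM missing for gene(s): %s",
             paste(setdiff(genes, names(lookup)), collapse = ", "))
    max(lookup[genes])
  }, numeric(1))
  linkages$max_fpkm <- vals
  linkages$expressed <- !is.na(vals) & vals > threshold
  linkages
}

#' Enhancer-to-enhancer contact counts
#'
#' For each region, the number of distinct other regions that share an
#' enriched contact record with it (self-contacts excluded).
#'
#' @param regions `GRanges` of regions.
#' @param contacts Contact records (only `enriched` rows are used when the
#'   flag is present).
#' @return Integer vector of partner counts, one per region.
#' @export
enhancer_enhancer_contacts <- function(regions, contacts) {
  n <- length(regions)
  counts <- integer(n)
  if ("enriched" %in% names(contacts))
    contacts <- contacts[contacts$enriched, , drop = FALSE]
  if (!nrow(contacts)) return(counts)
  an <- .contact_anchors(contacts)
  ov1 <- GenomicRanges::findOverlaps(regions, an$a1)
  ov2 <- GenomicRanges::findOverlaps(regions, an$a2)
  d1 <- data.table::data.table(rec = S4Vectors::subjectHits(ov1),
                               r1 = S4Vectors::queryHits(ov1))
  d2 <- data.table::data.table(rec = S4Vectors::subjectHits(ov2),
                               r2 = S4Vectors::queryHits(ov2))
  pairs <- merge(d1, d2, by = "rec", allow.cartesian = TRUE)
  pairs <- pairs[pairs$r1 != pairs$r2, ]
  if (!nrow(pairs)) return(counts)
  partners <- unique(rbind(
    data.frame(a = pairs$r1, b = pairs$r2),
    data.frame(a = pairs$r2, b = pairs$r1)))
  tab <- table(factor(partners$a, levels = seq_len(n)))
  as.integer(tab)
}

#' Write a linkage table as TSV
#' @param linkages Output of [linked_expression()].
#' @param path Output path.
#' @export
write_linkage <- function(linkages, path) {
  data.table::fwrite(linkages, path, sep = "\t")
  invisible(path)
}
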