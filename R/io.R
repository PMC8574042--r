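#' Readers and writers for the standard interchange formats
#'
#' BED/bedGraph/wiggle/GFF3 go through `rtracklayer`; tabular formats
#' (chrom sizes, contacts, expression, the dataset TSV) through
#' `data.table`.
#'
#' @name io
NULL

#' Read a two-column chrom.sizes TSV
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- data.table::fread(path, header = FALSE, col.names = c("chrom", "size"),
                          select = 1:2, data.table = FALSE)
  setNames(as.numeric(df$size), as.character(df$chrom))
}

#' Write a chrom.sizes TSV
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a signal track (bedGraph or wiggle)
#' @param path File path; format inferred from the extension
#'   (`.bg`/`.bedgraph` vs `.wig`).
#' @return `GRanges` with a `score` column.
#' @export
read_signal_track <- function(path) {
  fmt <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "wig"
         else "bedGraph"
  rtracklayer::import(path, format = fmt)
}

#' Write per-bin values as bedGraph
#'
#' Consecutive bins with identical values are collapsed into runs.
#'
#' @param bins A [tile_genome()] result.
#' @param values One value per bin.
#' @param path Output path.
#' @export
write_bedgraph <- function(bins, values, path) {
  gr <- bins$gr
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(values))
  dt[, run := data.table::rleid(chrom, score)]
  runs <- dt[, list(chrom = chrom[1L], start = start[1L],
                    end = end[.N], score = score[1L]), by = "run"][, run := NULL]
  collapsed <- GenomicRanges::GRanges(
    runs$chrom, IRanges::IRanges(runs$start + 1L, runs$end),
    score = runs$score)
  rtracklayer::export(collapsed, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED file of peaks/regions
#' @param path File path.
#' @return `GRanges`.
#' @export
read_peaks <- function(path) rtracklayer::import(path, format = "BED")

#' Write regions as BED
#' @param regions `GRanges`; `name`/`score` metadata columns are used if
#'   present.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Read a GFF3 gene annotation
#' @param path File path.
#' @return `GRanges` with `type`, `ID`, `Parent` metadata.
#' @export
read_annotation <- function(path) rtracklayer::import(path, format = "GFF3")

#' Write a gene annotation as GFF3
#' @param annotation `GRanges` with `type`/`ID`/`Parent` columns.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "GFF3")
  invisible(path)
}

#' Read BEDPE-like pairwise contact records
#'
#' Expects columns chrom1, start1, end1, chrom2, start2, end2, score
#' (0-based half-open anchors, observed/expected score).
#'
#' @param path File path.
#' @return A `contact_records` data frame (1-based closed anchors
#'   internally).
#' @export
read_contacts <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  names(df)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "score")
  df$start1 <- df$start1 + 1L
  df$start2 <- df$start2 + 1L
  class(df) <- c("contact_records", "data.frame")
  df
}

#' Write contact records as a BEDPE-like TSV
#' @param contacts A `contact_records` data frame (1-based internally).
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  out <- as.data.frame(contacts)
  out$start1 <- out$start1 - 1L
  out$start2 <- out$start2 - 1L
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a gene expression table (gene_id, fpkm)
#' @param path File path.
#' @return Data frame with columns `gene_id`, `fpkm`.
#' @export
read_fpkm <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  names(df)[1:2] <- c("gene_id", "fpkm")
  df
}

#' Write a gene expression table
#' @param fpkm Data frame with `gene_id`, `fpkm`.
#' @param path Output path.
#' @export
write_fpkm <- function(fpkm, path) {
  data.table::fwrite(fpkm[, c("gene_id", "fpkm")], path, sep = "\t")
  invisible(path)
}

#' Write a bin dataset as columnar TSV plus JSON sidecar
#'
#' The TSV holds chrom, start (0-based), end, one column per mark and the
#' label; the sidecar records bin width, feature order and normalization
#' bounds so the dataset round-trips exactly.
#'
#' @param dataset A [bin_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bin_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- dataset$bins$gr
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  df <- cbind(df, as.data.frame(dataset$features))
  df$label <- ifelse(dataset$labels, "enhancer", "non_enhancer")
  data.table::fwrite(df, file.path(dir, "dataset.tsv"), sep = "\t")
  sidecar <- list(bin_width = dataset$bins$width,
                  feature_order = dataset$feature_order,
                  chrom_sizes = as.list(dataset$bins$chrom_sizes))
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bin dataset written by [write_bin_dataset()]
#' @param dir Dataset directory.
#' @return A [bin_dataset()].
#' @export
read_bin_dataset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                 simplifyVector = TRUE)
  df <- data.table::fread(file.path(dir, "dataset.tsv"), data.table = FALSE)
  sizes <- unlist(sidecar$chrom_sizes)
  bins <- tile_genome(sizes, width = sidecar$bin_width)
  marks <- sidecar$feature_order
  X <- as.matrix(df[, marks, drop = FALSE])
  tracks <- lapply(setNames(marks, marks), function(m)
    signal_track(m, X[, m], normalized = TRUE))
  bin_dataset(bins, tracks, df$label == "enhancer")
}
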