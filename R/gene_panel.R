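#' Construct a gene panel
#'
#' A gene panel is a \link[GenomicRanges]{GRanges} holding, for each gene,
#' its coding intervals and one promoter interval (metadata columns
#' \code{gene} and \code{feature} in \code{c("coding", "promoter")}).
#' Intervals are validated to be non-overlapping within a gene, with the
#' promoter abutting or preceding the first coding interval.
#'
#' @param gr GRanges with mcols \code{gene} and \code{feature}.
#' @param panel_label free-text label stored in \code{metadata(gr)$panel_label}.
#' @return a validated GRanges of class membership \code{gene_panel}.
#' @export
gene_panel <- function(gr, panel_label = "panel") {
  stopifnot(methods::is(gr, "GRanges"),
            all(c("gene", "feature") %in% names(S4Vectors::mcols(gr))),
            all(gr$feature %in% c("coding", "promoter")))
  for (g in unique(gr$gene)) {
    sub <- gr[gr$gene == g]
    if (length(sub) > 1 &&
        any(IRanges::countOverlaps(IRanges::ranges(sub)) > 1)) {
      stop("overlapping intervals within gene ", g)
    }
    prom <- sub[sub$feature == "promoter"]
    cod <- sub[sub$feature == "coding"]
    if (length(prom) && length(cod) &&
        min(GenomicRanges::start(cod)) < max(GenomicRanges::end(prom))) {
      stop("promoter of gene ", g, " must abut or precede its coding intervals")
    }
  }
  S4Vectors::metadata(gr)$panel_label <- panel_label
  gr
}

# the 22 genes in which single-gene mutations cause SLE or an SLE-like
# interferon-pathway disease
.panel_gene_names <- c(
  "TREX1", "DNASE1", "DNASE1L3", "DNASE2", "C1QA", "C1QB", "C1QC", "C1R",
  "C1S", "C2", "C4A", "C4B", "RNASEH2A", "RNASEH2B", "RNASEH2C", "SAMHD1",
  "ADAR", "IFIH1", "ACP5", "TMEM173", "ISG15", "PRKCD")

#' The bundled monogenic-SLE gene panel (synthetic coordinates)
#'
#' Twenty-two genes known to cause either classical monogenic SLE or an
#' SLE-like type I interferonopathy.  Gene names are real; coordinates are
#' synthetic: each gene sits on its own contig \code{chrS1..chrS22} with a
#' 2 kb promoter abutting three 200 bp coding intervals, so that panels can
#' never be joined accidentally against a real reference genome.
#'
#' @return a \code{gene_panel} GRanges (88 intervals).
#' @export
example_gene_panel <- function() {
  n <- length(.panel_gene_names)
  per_gene <- 4L # promoter + 3 exons
  starts <- c(10001L, 12001L, 12801L, 13601L)
  ends <- c(12000L, 12200L, 13000L, 13800L)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(paste0("chrS", seq_len(n)), each = per_gene),
    ranges = IRanges::IRanges(start = rep(starts, n), end = rep(ends, n)),
    gene = rep(.panel_gene_names, each = per_gene),
    feature = rep(c("promoter", "coding", "coding", "coding"), n))
  gene_panel(gr, panel_label = "monogenic_SLE_22_synthetic")
}

#' Read / write a gene panel as BED
#'
#' BED uses 0-based half-open coordinates; the conversion is handled by
#' \pkg{rtracklayer}.  The BED name field stores \code{gene|feature}.
#'
#' @param panel a \code{gene_panel} GRanges.
#' @param path BED file path.
#' @export
write_panel_bed <- function(panel, path) {
  out <- panel
  out$name <- paste(panel$gene, panel$feature, sep = "|")
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = out$name)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  gr$gene <- vapply(parts, `[`, "", 1L)
  gr$feature <- vapply(parts, `[`, "", 2L)
  gr$name <- NULL
  gr$score <- NULL
  gene_panel(gr)
}

# panel membership of positions, restricted to the intervals relevant for an
# annotation class group: coding intervals for non-silent/silent coding
# classes, promoter intervals for promoter variants.
variant_in_panel <- function(chrom, pos, panel, feature = c("coding", "promoter")) {
  feature <- match.arg(feature)
  sub <- panel[panel$feature == feature]
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # query and panel deliberately share only some contigs
  suppressWarnings(
    GenomicRanges::countOverlaps(q, sub, ignore.strand = TRUE) > 0)
}
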