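# VCF / PED interfaces.  VCF reading and writing goes through
# VariantAnnotation; the package only assembles the in-memory VCF object
# (GT + PL on export; GT + PL + GP + FT after refinement).

.gt_string <- c("0/0", "0/1", "1/1")

.build_vcf <- function(variant_df, gt, pl = NULL, gp = NULL, ft = NULL,
                       filter = NULL) {
  samples <- colnames(gt)
  rr <- GenomicRanges::GRanges(
    seqnames = variant_df$chrom,
    ranges = IRanges::IRanges(start = variant_df$pos, width = 1L))
  names(rr) <- variant_df$variant_id
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(variant_df$ref),
    ALT = Biostrings::DNAStringSetList(as.list(variant_df$alt)),
    QUAL = rep(100, nrow(variant_df)),
    FILTER = filter %||% rep("PASS", nrow(variant_df)))
  geno_fmt <- S4Vectors::DataFrame(
    Number = c("1", "G", "1", "1"),
    Type = c("String", "Integer", "Float", "String"),
    Description = c("Genotype",
                    "Phred-scaled genotype likelihoods",
                    "Phred-scaled trio genotype posterior quality",
                    "Per-sample genotype filter (PASS or LOWGP)"),
    row.names = c("GT", "PL", "GP", "FT"))
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::geno(hdr) <- geno_fmt
  g <- list(GT = gt)
  if (!is.null(pl)) g$PL <- pl
  if (!is.null(gp)) g$GP <- gp
  if (!is.null(ft)) g$FT <- ft
  VariantAnnotation::VCF(
    rowRanges = rr, fixed = fixed,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = hdr),
    geno = S4Vectors::SimpleList(g))
}

#' Write the trio genotypes of a cohort as a multi-sample VCF
#'
#' Emits the common markers plus every rare variant carried by a trio
#' member, with GT and PL FORMAT fields (VCF 4.2, synthetic contigs
#' chrS*).  When a refinement result is supplied, child genotypes are
#' replaced by the refined calls and GP (posterior phred) and FT
#' (PASS/LOWGP) FORMAT fields are added.
#'
#' @param cohort a \code{trio_cohort}.
#' @param path output .vcf path (plain text).
#' @param refined optional \code{\link{refine_trios}} result.
#' @return the path, invisibly.
#' @export
write_trio_vcf <- function(cohort, path, refined = NULL) {
  fam <- cohort$samples$family_id[cohort$samples$role == "patient"]
  samples <- c(paste0(fam, "_P"), paste0(fam, "_M"), paste0(fam, "_F"))
  nf <- length(fam)
  nm <- nrow(cohort$markers)

  child <- if (is.null(refined)) cohort$geno$child_obs else refined$dosage
  dos <- cbind(t(child), t(cohort$geno$mother), t(cohort$geno$father))
  common_gt <- matrix(.gt_string[dos + 1L], nrow = nm,
                      dimnames = list(cohort$markers$variant_id, samples))
  # PL: children carry their simulated triples; parents confident triples
  pl <- array(0L, dim = c(nm, length(samples), 3))
  pl[, seq_len(nf), ] <- aperm(cohort$geno$child_pl, c(2, 1, 3))
  for (g in 0:2) {
    pl[, nf + seq_len(nf), g + 1] <- 30L * abs(t(cohort$geno$mother) - g)
    pl[, 2 * nf + seq_len(nf), g + 1] <- 30L * abs(t(cohort$geno$father) - g)
  }

  rare <- cohort$variants
  rare_car <- cohort$carriers[cohort$carriers$sample_id %in% samples, ]
  rare <- rare[rare$variant_id %in% rare_car$variant_id, ]
  rare_gt <- matrix("0/0", nrow(rare), length(samples),
                    dimnames = list(rare$variant_id, samples))
  if (nrow(rare_car)) {
    rid <- match(rare_car$variant_id, rare$variant_id)
    sid <- match(rare_car$sample_id, samples)
    keep <- !is.na(rid) & !is.na(sid)
    rare_gt[cbind(rid[keep], sid[keep])] <-
      .gt_string[rare_car$dosage[keep] + 1L]
  }
  rare_pl <- array(0L, dim = c(nrow(rare), length(samples), 3))
  rare_dos <- matrix(match(rare_gt, .gt_string) - 1L, nrow(rare))
  for (g in 0:2) rare_pl[, , g + 1] <- 30L * abs(rare_dos - g)

  vdf <- rbind(
    cohort$markers[c("variant_id", "chrom", "pos", "ref", "alt")],
    rare[c("variant_id", "chrom", "pos", "ref", "alt")])
  gt <- rbind(common_gt, rare_gt)
  pl_all <- array(0L, dim = c(nrow(vdf), length(samples), 3))
  pl_all[seq_len(nm), , ] <- pl
  pl_all[nm + seq_len(nrow(rare)), , ] <- rare_pl
  dimnames(pl_all) <- list(vdf$variant_id, samples, NULL)

  gp <- ft <- NULL
  if (!is.null(refined)) {
    gp <- matrix(99, nrow(vdf), length(samples),
                 dimnames = dimnames(gt))
    gp[seq_len(nm), seq_len(nf)] <- round(t(refined$phred), 2)
    ft <- matrix("PASS", nrow(vdf), length(samples),
                 dimnames = dimnames(gt))
    ft[seq_len(nm), seq_len(nf)][t(refined$flag)] <- "LOWGP"
  }
  vcf <- .build_vcf(vdf, gt, pl = pl_all, gp = gp, ft = ft)
  VariantAnnotation::writeVcf(vcf, path)
  # writeVcf does not put ##fileformat first for a hand-built header;
  # htslib insists on it as the opening line
  lines <- readLines(path)
  lines <- lines[!grepl("^##fileformat", lines)]
  writeLines(c("##fileformat=VCFv4.2", lines), path)
  invisible(path)
}

#' Read a trio VCF back into dosage matrices
#'
#' @param path VCF path.
#' @return list with \code{variants} (id, chrom, pos, ref, alt),
#'   \code{dosage} (variants x samples), and \code{pl} (variants x
#'   samples x 3 array, when present).
#' @export
read_trio_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- matrix(match(gt, .gt_string) - 1L, nrow(gt),
                   dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE)
  pl <- VariantAnnotation::geno(vcf)$PL
  list(variants = variants, dosage = dosage, pl = pl)
}

#' Write / read a 6-column PED pedigree file
#'
#' Columns: family, individual, father, mother, sex (1 = male,
#' 2 = female), phenotype (1 = unaffected, 2 = affected).
#'
#' @param pedigree data.frame as in \code{trio_cohort$pedigree}.
#' @param path file path.
#' @export
write_ped <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(ped) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  ped
}
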