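.openOut <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Read a raw variant panel from VCF
#'
#' Ingests a VCF with per-sample genotype (\code{GT}) and per-allele depth
#' (\code{AD}) fields, as produced by an upstream variant caller at forced
#' positions, and applies marker hygiene filters:
#' \itemize{
#'   \item markers with more than \code{maxAlleles} alleles (or no alternate
#'     allele) are dropped with a warning;
#'   \item markers whose fraction of heterozygous genotypes among
#'     non-missing genotypes exceeds \code{hetFractionMax} are dropped
#'     (heterozygous calls are not expected in fully homozygous material);
#'   \item fixed markers (no called cell carries the minor allele) are
#'     dropped when \code{dropFixed} is set.
#' }
#' All filters are evaluated on the full marker set in one pass, so the
#' surviving marker set does not depend on filter order.
#'
#' Samples may be haploid or fully homozygous diploid (diploid homozygous
#' genotypes collapse to one haplotype call; unphased heterozygous
#' genotypes become missing). If any phased heterozygous genotype is
#' present, every sample is split into two haplotype rows
#' \code{<sample>_A}/\code{<sample>_B}, each receiving the cell's full read
#' counts (reads cannot be apportioned between haplotypes from a VCF).
#' Absent depth fields yield zero reads. Calls asserted without reads are
#' preserved.
#'
#' @param path VCF file, plain or gzip-compressed.
#' @param opts list from \code{\link{ingestOptions}}.
#' @return a \code{\link{HaplotypePanel}} restricted to surviving biallelic
#'   markers; the per-marker drop log (\code{data.frame} with reason codes
#'   \code{MULTIALLELIC}/\code{HIGH_HET}/\code{FIXED}) is stored in
#'   \code{S4Vectors::metadata(panel)$dropLog}.
#' @export
readRawVcf <- function(path, opts = ingestOptions()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("no records in ", path)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  nAlt <- ifelse(is.na(alt) | alt == ".", 0L,
                 vapply(strsplit(alt, ",", fixed = TRUE), length, integer(1)))
  multi <- nAlt + 1L > opts$maxAlleles | nAlt == 0L
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF carries no GT field")
  samples <- colnames(gt)
  # genotype token -> allele pair (string functions drop dims; restore them)
  a1 <- matrix(sub("^([^/|]*)[/|]?.*$", "\\1", gt), nrow(gt), ncol(gt))
  a2 <- matrix(ifelse(grepl("[/|]", gt),
                      sub("^[^/|]*[/|](.*)$", "\\1", gt), a1),
               nrow(gt), ncol(gt))
  a1[a1 %in% c(".", "")] <- NA; a2[a2 %in% c(".", "")] <- NA
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  nonMissing <- !is.na(a1) | !is.na(a2)
  hetFrac <- ifelse(rowSums(nonMissing) > 0,
                    rowSums(het) / rowSums(nonMissing), 0)
  highHet <- hetFrac > opts$hetFractionMax
  phasedHet <- het & grepl("|", gt, fixed = TRUE)
  splitMode <- any(phasedHet, na.rm = TRUE)
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  .adCol <- function(k) {
    if (is.null(ad)) return(matrix(0L, nrow(gt), ncol(gt)))
    parts <- strsplit(ifelse(is.na(ad) | ad == ".", "0,0", ad), ",",
                      fixed = TRUE)
    m <- vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(p[k]))
      if (is.na(v)) 0L else v
    }, integer(1))
    matrix(m, nrow(gt), ncol(gt))
  }
  rr <- .adCol(1L)
  ar <- .adCol(2L)
  toCall <- function(a) ifelse(is.na(a), NA_integer_,
                               ifelse(a == "0", 0L,
                                      ifelse(a == "1", 1L, NA_integer_)))
  if (splitMode) {
    cl <- cbind(toCall(a1), toCall(a2))
    rr <- cbind(rr, rr); ar <- cbind(ar, ar)
    haps <- c(paste0(samples, "_A"), paste0(samples, "_B"))
  } else {
    hom <- ifelse(het, NA, a1)  # unphased het -> missing
    cl <- toCall(hom)
    haps <- samples
  }
  cl <- matrix(cl, nrow(gt), length(haps))
  nRef <- rowSums(cl == 0L, na.rm = TRUE)
  nAltC <- rowSums(cl == 1L, na.rm = TRUE)
  fixed <- (nRef == 0L | nAltC == 0L)
  drop <- multi | highHet | (opts$dropFixed & fixed)
  if (any(multi))
    warning(sum(multi), " marker(s) dropped: more than ", opts$maxAlleles,
            " alleles or no alternate allele")
  if (all(drop))
    stop("no markers survive the ingest filters (empty panel)")
  reason <- paste0(ifelse(multi, "MULTIALLELIC;", ""),
                   ifelse(highHet, "HIGH_HET;", ""),
                   ifelse(opts$dropFixed & fixed, "FIXED;", ""))
  dropLog <- data.frame(
    chrom = chrom[drop], pos = pos[drop],
    markerId = ifelse(is.na(fix[drop, "ID"]), ".", fix[drop, "ID"]),
    reason = sub(";$", "", reason[drop]),
    stringsAsFactors = FALSE, row.names = NULL)
  keep <- which(!drop)
  markers <- data.frame(
    chrom = chrom[keep], pos = pos[keep], ref = ref[keep], alt = alt[keep],
    isSnp = !grepl("^<", alt[keep]), stringsAsFactors = FALSE)
  id <- fix[keep, "ID"]
  if (!all(is.na(id) | id == ".")) markers$markerId <- id
  panel <- HaplotypePanel(cl[keep, , drop = FALSE],
                          rr[keep, , drop = FALSE],
                          ar[keep, , drop = FALSE],
                          markers, haplotypeIds = haps)
  S4Vectors::metadata(panel)$dropLog <- dropLog
  panel
}

#' Write a panel to VCF
#'
#' One sample per haplotype; calls encoded as haploid genotypes (\code{0},
#' \code{1}, \code{.} for missing), read counts in \code{AD}, and — when a
#' depth track is supplied — the estimated read-depth per genotype in a
#' numeric \code{ED} field, rounded to 2 decimals (\code{.} where not
#' covered).
#'
#' @param panel a non-empty \code{\link{HaplotypePanel}}.
#' @param path output file; gzip-compressed when it ends in \code{.gz}.
#' @param depth optional \code{\linkS4class{DepthTrack}} conformable with
#'   \code{panel}.
#' @return \code{path}, invisibly.
#' @export
writeImputedVcf <- function(panel, path, depth = NULL) {
  if (nrow(panel) == 0L || ncol(panel) == 0L)
    stop("refusing to write an empty panel")
  info <- markerInfo(panel)
  cl <- calls(panel)
  rr <- refReads(panel)
  ar <- altReads(panel)
  dm <- if (!is.null(depth)) depthMatrix(depth) else NULL
  if (!is.null(dm)) stopifnot(identical(dim(dm), dim(cl)))
  con <- .openOut(path)
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=blockcall",
    sprintf("##contig=<ID=%s>", unique(info$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    if (!is.null(dm))
      "##FORMAT=<ID=ED,Number=1,Type=Float,Description=\"Estimated read-depth after block merging\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", haplotypeIds(panel)), collapse = "\t")), con)
  gtChar <- matrix(".", nrow(cl), ncol(cl))
  gtChar[which(cl == 0L)] <- "0"
  gtChar[which(cl == 1L)] <- "1"
  cells <- matrix(paste0(gtChar, ":", rr, ",", ar), nrow(cl), ncol(cl))
  if (!is.null(dm)) {
    ed <- ifelse(is.na(dm), ".", sprintf("%.2f", dm))
    cells <- matrix(paste0(cells, ":", ed), nrow(cl), ncol(cl))
  }
  fmt <- if (is.null(dm)) "GT:AD" else "GT:AD:ED"
  lines <- paste(info$chrom, info$pos, info$markerId, info$ref, info$alt,
                 ".", "PASS", ".", fmt,
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a block library from TSV
#'
#' Tab-separated with header
#' \code{block_id chrom start_marker end_marker members}; marker columns are
#' 1-based inclusive indices into the panel's SNP marker list for that
#' chromosome, \code{members} a comma-separated list of haplotype
#' identifiers. Indices are converted to the internal 0-based half-open
#' convention.
#'
#' @param path TSV file, plain or gzip-compressed.
#' @param panel optional \code{\link{HaplotypePanel}}; when given, the
#'   library is validated against it.
#' @return a \code{\link{BlockLibrary}}.
#' @export
readBlockLibrary <- function(path, panel = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer",
                                  "integer", "character"),
                   stringsAsFactors = FALSE)
  need <- c("block_id", "chrom", "start_marker", "end_marker", "members")
  if (!identical(colnames(df), need))
    stop("block-library header must be: ", paste(need, collapse = " "))
  if (nrow(df) && any(df$start_marker > df$end_marker))
    stop("start_marker > end_marker in block library")
  lib <- BlockLibrary(blockId = df$block_id, chrom = df$chrom,
                      startM = df$start_marker - 1L, endM = df$end_marker,
                      members = strsplit(df$members, ",", fixed = TRUE))
  if (!is.null(panel)) validateLibrary(lib, panel)
  lib
}

#' Write a block library to TSV
#'
#' The inverse of \code{\link{readBlockLibrary}}: 1-based inclusive marker
#' indices, blocks sorted by (chrom, start, block_id). Overlapping blocks
#' are legal and emitted as-is.
#'
#' @param lib a \code{\link{BlockLibrary}}.
#' @param path output file; gzip-compressed when it ends in \code{.gz}.
#' @return \code{path}, invisibly.
#' @export
writeBlockLibrary <- function(lib, path) {
  o <- order(lib@chrom, lib@startM, lib@blockId)
  con <- .openOut(path)
  on.exit(close(con))
  writeLines("block_id\tchrom\tstart_marker\tend_marker\tmembers", con)
  if (length(lib))
    writeLines(paste(lib@blockId[o], lib@chrom[o], lib@startM[o] + 1L,
                     lib@endM[o],
                     vapply(lib@members[o], paste, character(1),
                            collapse = ","),
                     sep = "\t"), con)
  invisible(path)
}

#' Write CNV calls as a BED-style track
#'
#' 0-based half-open bp intervals (converted from the calls' 1-based
#' inclusive coordinates) with columns chrom, start, end, name (the
#' haplotype), score (mean depth ratio x 1000, truncated) and kind
#' (\code{DUP}/\code{DEL}).
#'
#' @param cnvCalls \code{data.frame} as returned by
#'   \code{\link{classifyCnv}} (may be empty).
#' @param path output file; gzip-compressed when it ends in \code{.gz}.
#' @return \code{path}, invisibly.
#' @export
writeCnvTracks <- function(cnvCalls, path) {
  con <- .openOut(path)
  on.exit(close(con))
  if (nrow(cnvCalls))
    writeLines(paste(cnvCalls$chrom, cnvCalls$startBp - 1L, cnvCalls$endBp,
                     cnvCalls$haplotype, trunc(cnvCalls$meanRatio * 1000),
                     cnvCalls$kind, sep = "\t"), con)
  invisible(path)
}
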