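#' Worked toy example: 5 haplotypes, 10 SNPs, 3 blocks
#'
#' A small didactic dataset used throughout the documentation and tests.
#' Five haplotypes (H1..H5) are typed at ten SNPs (placed at 100 bp
#' spacing on \code{chr1}); every called cell carries exactly one read.
#' Three haplotype blocks encode the local IBD structure: a "red" block
#' \{H1,H2,H3\} over SNPs 1-10, a "green" block \{H4,H5\} over SNPs 1-5 and
#' a "blue" block \{H1,H2,H3,H4\} over SNPs 6-10 (red and blue overlap).
#'
#' Calls present in the raw panel:
#' \itemize{
#'   \item SNP 1: H2 = ALT, H3 = ALT (one read each);
#'   \item SNP 4: H2 = ALT, H3 = ALT (one read each);
#'   \item SNP 5: H1 = ALT, H2 = REF (one read each).
#' }
#' All other cells are missing with zero reads. With the default
#' self-weight 5 this reproduces the hand calculations quoted in the
#' function examples: weighted support 5:1 at (H1, SNP 5), 2:0 at
#' (H1, SNP 1); estimated depths 2/7, 6/7, 6/7, 0, 0 at SNP 4; marker
#' average 0.4X; duplications for H2/H3 and deletions for H4/H5 at SNP 4
#' when classifying without smoothing.
#'
#' @return list with components \code{panel}
#'   (\code{\link{HaplotypePanel}}) and \code{library}
#'   (\code{\link{BlockLibrary}}).
#' @examples
#' toy <- toyExample()
#' coverageFraction(toy$library, toy$panel)
#' @export
toyExample <- function() {
  haps <- paste0("H", 1:5)
  cl <- matrix(NA_integer_, 10, 5, dimnames = list(NULL, haps))
  rr <- matrix(0L, 10, 5, dimnames = list(NULL, haps))
  ar <- matrix(0L, 10, 5, dimnames = list(NULL, haps))
  cl[1, c("H2", "H3")] <- 1L; ar[1, c("H2", "H3")] <- 1L
  cl[4, c("H2", "H3")] <- 1L; ar[4, c("H2", "H3")] <- 1L
  cl[5, "H1"] <- 1L; ar[5, "H1"] <- 1L
  cl[5, "H2"] <- 0L; rr[5, "H2"] <- 1L
  markers <- data.frame(chrom = "chr1", pos = (1:10) * 100L,
                        ref = "A", alt = "T")
  panel <- HaplotypePanel(cl, rr, ar, markers, haplotypeIds = haps)
  lib <- BlockLibrary(
    blockId = c("red", "green", "blue"),
    chrom = rep("chr1", 3),
    startM = c(0L, 0L, 5L), endM = c(10L, 5L, 10L),
    members = list(c("H1", "H2", "H3"), c("H4", "H5"),
                   c("H1", "H2", "H3", "H4")))
  list(panel = panel, library = lib)
}
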