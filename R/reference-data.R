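#' Salt-responsive DE-lncRNA loci reported in rice FL478 and IR29
#'
#' The published set of 13 differentially expressed lncRNAs detected in
#' rice roots after 24 h of 150 mM NaCl: four in the salt-tolerant
#' genotype FL478 and nine in its salt-sensitive parent IR29. Coordinates
#' are genomic positions on the japonica (IRGSP-1.0) reference; `length`
#' is the printed locus length, which equals `end - start` under
#' half-open arithmetic; `log2fc` is salt vs. control. Loci named
#' `lncRNA.1` and `lncRNA.4` were detected in both genotypes at
#' overlapping coordinates.
#'
#' Used by examples and validation code as a worked input for coordinate
#' arithmetic, differential-expression calling and shared-locus
#' detection.
#'
#' @return `data.frame` with columns `genotype` (`FL478`/`IR29`),
#'   `transcript_id`, `name`, `chrom`, `start`, `end`, `length`,
#'   `log2fc`, `class_code`.
#' @examples
#' tab <- rice_de_lncrnas()
#' all(tab$end - tab$start == tab$length)
#' @export
rice_de_lncrnas <- function() {
  data.frame(
    genotype = c(rep("FL478", 4), rep("IR29", 9)),
    transcript_id = c("TCONS_00038460", "TCONS_00088492", "TCONS_00110513",
                      "TCONS_00069370", "TCONS_00038953", "TCONS_00109665",
                      "TCONS_00014111", "TCONS_00070354", "TCONS_00015930",
                      "TCONS_00003216", "TCONS_00073667", "TCONS_00028639",
                      "TCONS_00076916"),
    name = c("lncRNA.1", "lncRNA.2-FL", "lncRNA.3-FL", "lncRNA.4",
             "lncRNA.1", "lncRNA.2-IR", "lncRNA.3-IR", "lncRNA.4",
             "lncRNA.5-IR", "lncRNA.6-IR", "lncRNA.7-IR", "lncRNA.8-IR",
             "lncRNA.9-IR"),
    chrom = c("chr2", "chr6", "chr9", "chr4",
              "chr2", "chr8", "chr1", "chr4", "chr10", "chr1", "chr4",
              "chr1", "chr5"),
    start = c(9106571, 21764438, 19868030, 25515690,
              9106569, 13484779, 23750606, 25515690, 8069944, 24908220,
              24983145, 2932659, 26093812),
    end = c(9107483, 21765266, 19868740, 25516406,
            9107483, 13485797, 23751636, 25516422, 8070766, 24909529,
            24983890, 2933342, 26095238),
    length = c(912, 828, 710, 716,
               914, 1018, 1030, 732, 822, 1309, 745, 683, 1426),
    log2fc = c(-1.84777, 1.33505, -1.84449, 1.3109,
               -2.84421, 2.43485, 1.77214, 1.20362, -19.3908, -1.70111,
               2.11511, 1.21378, 1.81551),
    class_code = c("o", "o", "o", "o",
                   "o", "u", "o", "o", "o", "o", "u", "o", "o"),
    stringsAsFactors = FALSE)
}

#' Reported lncRNA category tallies in rice FL478
#'
#' The per-category counts of the 132 lncRNAs identified in the
#' salt-tolerant genotype FL478: 93 sense, 8 antisense, 27 lincRNA and
#' 4 intronic.
#'
#' @return Named integer vector over the four lncRNA categories, plus an
#'   attribute `total` with the reported overall count.
#' @export
rice_fl478_class_counts <- function() {
  structure(c(sense = 93L, antisense = 8L, lincRNA = 27L, intronic = 4L),
            total = 132L)
}
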