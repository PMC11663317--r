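# Fixed synthetic flanking sequences shipped with the package.
#
# These are NOT the GRCh38 flanks of the C9orf72 locus: they are synthetic
# 120 bp GC-containing sequences with six CpG dinucleotides each (two of them
# within 35 bp of the outer read end), no internal GGGGCC occurrence, and no
# repeated 20-mer, so that anchor matching within a read is unambiguous.
# Shipping fixed sequences keeps the "flank + repeat tract + flank" read
# structure without requiring any genome download.
.C9_FLANK_LEFT <- paste0(
  "GAGCTCTAGCGTGTCTACAGGTGTACCGGAGCCATGATGGAGCCCTCTTG",
  "CACACGAGCCATCAACCTAGAGAGCATAACGAGGTAACTACACTTCAGGC",
  "GCCATGTGATTACGCTTCCA"
)
.C9_FLANK_RIGHT <- paste0(
  "CTAGACGCAAGGTATCCACGATGTCAAAAAAGCCAGTTCCGCATAGACTA",
  "CTTGTCCTAAGCACGATCCATCAAGGTAAAGTCACAGTATGCGAAGCAAG",
  "GCAGTGTCGGTCCAAGAATC"
)

#' Synthetic flanking sequences of the simulated repeat locus
#'
#' Returns the fixed non-repeat sequences placed on each side of the GGGGCC
#' tract by [simulate_cohort()]. With `flank_length < 120` the portion
#' adjacent to the tract is kept (the outer bases are dropped), so the tract
#' junctions are identical for every choice of flank length.
#'
#' @param flank_length Number of bases to keep on each side (40 to 120).
#' @return A list with elements `left` and `right` (character scalars).
#' @examples
#' nchar(c9_flanks()$left)
#' @export
c9_flanks <- function(flank_length = 120L) {
  flank_length <- as.integer(flank_length)
  if (is.na(flank_length) || flank_length < 40L || flank_length > 120L) {
    abort("`flank_length` must be between 40 and 120 bases.")
  }
  list(
    left = substr(.C9_FLANK_LEFT, 120L - flank_length + 1L, 120L),
    right = substr(.C9_FLANK_RIGHT, 1L, flank_length)
  )
}

#' Anchor sequences used to decide whether a read spans the locus
#'
#' The anchors are the outermost `width` bases of each flank. A read that
#' contains both anchors necessarily contains both complete flanks and hence
#' the full repeat tract between them.
#'
#' @param flank_length Flank length in use (see [c9_flanks()]).
#' @param width Anchor width in bases; at least 20 to avoid spurious matches.
#' @return A list with character elements `left` and `right`.
#' @seealso [spans_locus()]
#' @export
locus_anchors <- function(flank_length = 120L, width = 20L) {
  width <- as.integer(width)
  if (is.na(width) || width < 20L) {
    abort("Anchor `width` must be at least 20 bases (shorter anchors risk ambiguous matches).")
  }
  fl <- c9_flanks(flank_length)
  if (width > nchar(fl$left)) abort("Anchor `width` exceeds the flank length.")
  list(
    left = substr(fl$left, 1L, width),
    right = substr(fl$right, nchar(fl$right) - width + 1L, nchar(fl$right))
  )
}
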