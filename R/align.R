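#' Global pairwise alignment score and identity
#'
#' Needleman-Wunsch alignment with the pipeline's fixed scoring scheme
#' (match +1, mismatch -1, gap -2). Identity is the fraction of matching
#' columns over all alignment columns, gaps included, which is the definition
#' used both for OTU clustering and for reference matching.
#'
#' @param a,b DNA strings (A/C/G/T).
#' @return list with `score` (alignment score) and `identity` (fraction in
#'   `[0, 1]`).
#' @export
align_stats <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  columns <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       identity = Biostrings::nmatch(aln) / columns)
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string; IUPAC degeneracy codes are complemented to their
#'   counterparts (R/Y, K/M, B/V, D/H; S, W and N are self-complementary).
#' @return the reverse complement string.
#' @export
reverse_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(toupper(x), NULL),
                function(s) paste(rev(s), collapse = ""),
                character(1)))
}
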