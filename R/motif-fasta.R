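#' @include AllClasses.R
NULL

## amino-acid alphabet without the acidic residues
.NON_ACIDIC <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       c("D", "E"))

#' Generate synthetic sequences carrying the Tri-Asp motif
#'
#' Each sequence has Asp exactly at positions i, i+4 and i+10 for its
#' requested motif start i (the 11-residue Tri-Asp span) and random
#' non-acidic residues (no D or E) everywhere else, so the strict
#' scanner finds exactly one hit per sequence at a known location.
#'
#' @param n number of sequences (0 gives an empty set)
#' @param motifStart 1-based motif start position(s), recycled over
#'   sequences
#' @param length sequence length (must accommodate motifStart + 10)
#' @param seed RNG seed
#' @param path optional FASTA output file
#' @return a \code{Biostrings::AAStringSet} (invisibly also written to
#'   \code{path} if given)
#' @examples
#' generateMotifFasta(2, motifStart = 5, length = 30, seed = 1)
#' @export
generateMotifFasta <- function(n, motifStart = 252, length = 300,
                               seed = NULL, path = NULL) {
  stopifnot(n >= 0, all(motifStart >= 1))
  if (any(motifStart + 10 > length))
    stop("motif position too close to sequence end: need length >= ",
         max(motifStart) + 10)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    out <- Biostrings::AAStringSet()
  } else {
    starts <- rep(motifStart, length.out = n)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(.NON_ACIDIC, length, replace = TRUE)
      p <- starts[i]
      s[c(p, p + 4, p + 10)] <- "D"
      paste(s, collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- sprintf("synthetic_motif_%03d_start%d",
                          seq_len(n), starts)
  }
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}
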