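#' @useDynLib anigap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats density runif rbinom setNames pnorm
#' @importFrom utils read.delim write.table
NULL

.BASES <- c("A", "C", "G", "T")

# character sequence -> integer codes A=0 C=1 G=2 T=3, other = -1
seq_codes <- function(s) {
  map <- rep(-1L, 128L)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("a")] <- 0L
  map[utf8ToInt("C")] <- 1L; map[utf8ToInt("c")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("g")] <- 2L
  map[utf8ToInt("T")] <- 3L; map[utf8ToInt("t")] <- 3L
  map[utf8ToInt(s)]
}

codes_to_seq <- function(codes) {
  chars <- c("N", .BASES)[codes + 2L]
  paste(chars, collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Ungapped percent identity of two sequences
#'
#' Position-by-position identity over the common length of two nucleotide
#' sequences, as used to score read or fragment mappings: a single mismatch on
#' a 100 bp sequence lowers the identity by exactly 1 percentage point, and by
#' 0.4 points on a 250 bp sequence.
#'
#' @param a,b character scalars (nucleotide sequences) or integer code vectors.
#' @return percent identity in `[0, 100]`.
#' @export
#' @examples
#' sequence_identity(strrep("A", 100), paste0(strrep("A", 99), "C"))  # 99
sequence_identity <- function(a, b) {
  if (is.character(a)) a <- seq_codes(a)
  if (is.character(b)) b <- seq_codes(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  .hamming_identity_cpp(a, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
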