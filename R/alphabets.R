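# Canonical symbol orders.  Mononucleotide columns are A,C,G,T; dinucleotide
# columns are AA,AC,...,TT in row-major order (first base varies slowest).
MONO_ALPHABET <- c("A", "C", "G", "T")
DI_ALPHABET <- paste0(rep(MONO_ALPHABET, each = 4L), rep(MONO_ALPHABET, 4L))

# Complement permutation on A,C,G,T indices.
COMP_PERM <- c(4L, 3L, 2L, 1L)

# Dinucleotide reverse-complement permutation: XY -> comp(Y)comp(X).
DI_RC_PERM <- {
  x <- rep(seq_len(4L), each = 4L)
  y <- rep(seq_len(4L), 4L)
  4L * (COMP_PERM[y] - 1L) + COMP_PERM[x]
}

di_index <- function(x, y) 4L * (x - 1L) + y

alphabet_symbols <- function(alphabet) {
  switch(alphabet,
    mono = MONO_ALPHABET,
    di = DI_ALPHABET,
    abort(sprintf("unknown alphabet '%s'", alphabet))
  )
}

alphabet_of_width <- function(width) {
  if (width == 4L) "mono" else if (width == 16L) "di" else
    abort(sprintf("matrix width %d is neither 4 (mono) nor 16 (di)", width))
}

# Number of nucleotides covered by a motif matrix: L for mono, D + 1 for di.
motif_span <- function(weights) {
  nrow(weights) + if (ncol(weights) == 16L) 1L else 0L
}

# Integer encoding of a DNA string: A,C,G,T -> 1..4, anything else (N etc.)
# -> 5.  Lowercase is treated as uppercase.
encode_dna_int <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  m <- match(chars, MONO_ALPHABET)
  m[is.na(m)] <- 5L
  m
}

# Dinucleotide codes 1..16 for consecutive base pairs; pairs touching an
# ambiguous base get code 17.
encode_di_int <- function(mono_int) {
  n <- length(mono_int)
  if (n < 2L) return(integer(0L))
  x <- mono_int[-n]
  y <- mono_int[-1L]
  code <- di_index(x, y)
  code[x == 5L | y == 5L] <- 17L
  code
}

#' One-hot encode a DNA sequence
#'
#' Produces the indicator matrix used by convolutional motif scanning: one row
#' per position (mono) or per adjacent base pair (di), one column per symbol
#' of the alphabet.  Ambiguous bases (anything outside A/C/G/T, e.g. `N`)
#' yield all-zero rows; lowercase is treated as uppercase.
#'
#' @param seq A single DNA sequence as a character string.
#' @param alphabet `"mono"` for an n x 4 matrix over A,C,G,T, or `"di"` for an
#'   (n-1) x 16 matrix over AA,AC,...,TT (row-major order).
#' @return An integer indicator matrix with symbol column names.
#' @examples
#' encode_one_hot("ACGT")
#' encode_one_hot("ACN", alphabet = "di")
#' @export
encode_one_hot <- function(seq, alphabet = c("mono", "di")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L)
  syms <- alphabet_symbols(alphabet)
  code <- encode_dna_int(seq)
  if (alphabet == "di") code <- encode_di_int(code)
  out <- matrix(0L, nrow = length(code), ncol = length(syms),
                dimnames = list(NULL, syms))
  ok <- code <= length(syms)
  out[cbind(which(ok), code[ok])] <- 1L
  out
}
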