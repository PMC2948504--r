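#' @keywords internal
#' @useDynLib cotscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Nucleotide alphabet used throughout: A, C, G, T plus the ambiguity code N.
## Internally bases are 2-bit coded A=0, C=1, G=2, T=3; N maps to NA and any
## window containing it is skipped (an ambiguous base can never match under
## Hamming semantics).

DNA_BASES <- c("A", "C", "G", "T")

.code_table <- local({
  tab <- rep(NA_integer_, 127L)
  tab[utf8ToInt("A")] <- 0L
  tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L
  tab[utf8ToInt("T")] <- 3L
  tab
})

#' Convert a DNA string to integer base codes
#'
#' @param s single DNA string over \{A,C,G,T,N\}.
#' @return integer vector, one code per base (A=0, C=1, G=2, T=3, N=NA).
#' @keywords internal
dna_codes <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  v <- utf8ToInt(s)
  if (length(v) == 0L) return(integer(0))
  if (any(v < 1L) || any(v > 126L)) {
    stop("invalid DNA character (non-ASCII) in sequence", call. = FALSE)
  }
  codes <- .code_table[v]
  bad <- is.na(codes) & v != utf8ToInt("N")
  if (any(bad)) {
    stop(sprintf("invalid DNA character '%s' at position %d",
                 intToUtf8(v[which(bad)[1L]]), which(bad)[1L]), call. = FALSE)
  }
  codes
}

codes_to_dna <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Length-preserving involution over the \{A,C,G,T,N\} alphabet; N maps to N.
#'
#' @param s single DNA string.
#' @return the reverse complement, 5'->3'.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (grepl("[^ACGTN]", s)) {
    stop("reverse_complement(): sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  if (nchar(s) == 0L) return(s)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

#' Encode a fixed-length DNA word as an integer key
#'
#' Bijection between words over \{A,C,G,T\} of a given length and the integers
#' `[0, 4^length)`, with A=0 ... T=3 and the first base most significant.
#' Words containing N are not encodable and yield `NA` so the caller can skip
#' the window.
#'
#' @param s DNA word.
#' @return integer key, or `NA` if the word contains N.
#' @examples
#' encode_word("AAAAAAAAA") # 0
#' encode_word("TTTTTTTTT") # 262143
#' @export
encode_word <- function(s) {
  codes <- dna_codes(s)
  w <- length(codes)
  if (w < 1L || w > 15L) stop("word length must be in [1, 15]", call. = FALSE)
  if (anyNA(codes)) return(NA_integer_)
  key <- 0L
  for (j in seq_len(w)) key <- key * 4L + codes[j]
  key
}

#' Decode an integer key back to its DNA word
#'
#' @param key integer in `[0, 4^word_size)`.
#' @param word_size word length.
#' @return DNA string of length `word_size`.
#' @export
decode_word <- function(key, word_size) {
  stopifnot(length(key) == 1L, !is.na(key), key >= 0, key < 4^word_size)
  digs <- integer(word_size)
  key <- as.double(key)
  for (p in word_size:1) {
    digs[p] <- key %% 4
    key <- key %/% 4
  }
  paste(DNA_BASES[digs + 1L], collapse = "")
}

## All word keys over a coded sequence by Horner's rule; windows containing
## an N come out NA. Max key 4^w - 1 fits an R integer for w <= 15.
window_keys <- function(codes, word_size) {
  n <- length(codes) - word_size + 1L
  if (n < 1L) return(integer(0))
  key <- integer(n)
  for (j in seq_len(word_size)) key <- key * 4L + codes[j:(n + j - 1L)]
  key
}

## Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, base_composition = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_composition),
        collapse = "")
}
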