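## Hamming-ball enumeration for seed words.
##
## A word of length w is held as base-4 digits (position 1 most significant).
## For every position p and substitution step d in {1,2,3} the key delta is
##   M[p, d] = (((digit[p] + d) mod 4) - digit[p]) * 4^(w - p),
## a w x 3 matrix. Which (position, step) combinations realise a variant at
## exact distance m is independent of the word, so those index tuples are
## precomputed once per (w, m) and each word only needs M plus vector adds.

.variant_index_cache <- new.env(parent = emptyenv())

## Matrix of linear indices into the w x 3 delta matrix: one row per variant
## at exact distance d, d columns.
variant_index <- function(word_size, d) {
  key <- sprintf("%d_%d", word_size, d)
  got <- .variant_index_cache[[key]]
  if (!is.null(got)) return(got)
  pos <- utils::combn(word_size, d)            # d x n_comb
  steps <- as.matrix(expand.grid(rep(list(1:3), d)))
  n_comb <- ncol(pos)
  n_steps <- nrow(steps)
  idx <- matrix(0L, nrow = n_comb * n_steps, ncol = d)
  for (jj in seq_len(d)) {
    p <- rep(pos[jj, ], each = n_steps)
    st <- rep(steps[, jj], times = n_comb)
    idx[, jj] <- (st - 1L) * word_size + p     # column-major into M
  }
  .variant_index_cache[[key]] <- idx
  idx
}

word_digits <- function(key, word_size) {
  digs <- integer(word_size)
  key <- as.double(key)
  for (p in word_size:1) {
    digs[p] <- key %% 4
    key <- key %/% 4
  }
  as.integer(digs)
}

## Integer keys of every word at Hamming distance exactly d from `key`.
hamming_neighbor_keys <- function(key, word_size, d) {
  if (d == 0L) return(as.integer(key))
  digs <- word_digits(key, word_size)
  wt <- 4^(word_size - seq_len(word_size))
  M <- outer(seq_len(word_size), 1:3,
             function(p, st) (((digs[p] + st) %% 4L) - digs[p]) * wt[p])
  idx <- variant_index(word_size, d)
  if (d == 1L) {
    as.integer(key + M[idx[, 1L]])
  } else {
    # c(idx) forces linear indexing (a 2-column idx would otherwise be
    # taken as (row, col) pairs)
    as.integer(key + rowSums(matrix(M[c(idx)], nrow = nrow(idx))))
  }
}

#' Number of DNA words within a Hamming ball
#'
#' Count of distinct equal-length DNA words within Hamming distance `k` of a
#' fixed word: `sum_{i=0..k} choose(L, i) * 3^i`.
#'
#' @param L word length.
#' @param k maximum Hamming distance.
#' @return the ball size (a count).
#' @export
hamming_ball_size <- function(L, k) {
  stopifnot(L >= 1, k >= 0, k <= L)
  sum(choose(L, 0:k) * 3^(0:k))
}

#' Enumerate all variants of a word within a mismatch budget
#'
#' Expands a seed word into every distinct word within Hamming distance
#' `max_mm`, each annotated with its exact distance. This is the seed-variant
#' expansion that lets a word-size-9 exact-location table answer mismatched
#' queries.
#'
#' @param word DNA word over \{A,C,G,T\}.
#' @param max_mm maximum Hamming distance (0 to `nchar(word)`).
#' @return data.frame with columns `variant` (character) and `mismatches`
#'   (integer, the exact distance); `sum(choose(w, 0:max_mm) * 3^(0:max_mm))`
#'   rows in total.
#' @export
enumerate_variants <- function(word, max_mm) {
  codes <- dna_codes(word)
  w <- length(codes)
  stopifnot(w >= 1L, w <= 15L, max_mm >= 0L, max_mm <= w)
  if (anyNA(codes)) stop("word contains N; variants are undefined", call. = FALSE)
  key <- encode_word(word)
  keys <- lapply(0:max_mm, function(d) hamming_neighbor_keys(key, w, d))
  data.frame(
    variant = unlist(lapply(keys, function(ks) {
      vapply(ks, decode_word, character(1), word_size = w)
    })),
    mismatches = rep(0:max_mm, lengths(keys)),
    stringsAsFactors = FALSE
  )
}
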