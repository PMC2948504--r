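## The seed table: for every possible word of the configured size (default 9,
## a key space of 4^9 = 262,144), the exact location of every occurrence in
## the target space. Looking up any fixed-length word is then a direct slice.
##
## Storage is a compressed location table: all windows of all records are
## 2-bit encoded to integer keys and stably ordered by key; `starts` gives
## the slice boundaries per key (length 4^word_size + 1). Within a key,
## locations are automatically sorted by (record, offset) and duplicate-free
## because each window occurs once.

#' Build a seed index over a target space
#'
#' @param ts a `target_space`.
#' @param word_size seed word length; the key space is `4^word_size`
#'   (262,144 at the default 9). Must lie in `[4, 15]` so keys fit an R
#'   integer. Windows containing N are skipped, not indexed.
#' @return an object of class `seed_index`.
#' @export
build_seed_index <- function(ts, word_size = 9L) {
  stopifnot(inherits(ts, "target_space"))
  word_size <- as.integer(word_size)
  if (word_size < 4L || word_size > 15L) {
    stop("word_size must be in [4, 15]", call. = FALSE)
  }
  nrec <- length(ts$seq)
  if (nrec == 0L) stop("target space has no records", call. = FALSE)
  keys_l <- offs_l <- recs_l <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    codes <- dna_codes(ts$seq[[r]])
    k <- window_keys(codes, word_size)
    ok <- which(!is.na(k))
    keys_l[[r]] <- k[ok]
    offs_l[[r]] <- ok - 1L           # 0-based offsets
    recs_l[[r]] <- rep.int(r, length(ok))
  }
  keys <- unlist(keys_l, use.names = FALSE)
  offs <- unlist(offs_l, use.names = FALSE)
  recs <- unlist(recs_l, use.names = FALSE)
  ord <- order(keys)                  # stable: keeps (rec, offset) order
  counts <- tabulate(keys + 1L, nbins = 4^word_size)
  structure(
    list(word_size = word_size,
         starts = c(0, cumsum(counts)),
         rec = recs[ord], off = offs[ord],
         seq_id = ts$seq_id, gene_id = ts$gene_id, rec_len = ts$len,
         mode = ts$mode,
         n_records = nrec,
         n_locations = length(keys),
         n_keys_occupied = sum(counts > 0L),
         keyspace_size = 4^word_size),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf(paste0("<seed_index> word_size=%d (key space %s), %d record(s), ",
                     "%d location(s), %d/%s keys occupied\n"),
              x$word_size, format(x$keyspace_size, big.mark = ","),
              x$n_records, x$n_locations, x$n_keys_occupied,
              format(x$keyspace_size, big.mark = ",")))
  invisible(x)
}

## Vectorised slice of the location table for many integer keys at once.
## Returns parallel vectors rec/off plus `key_group` mapping each location
## back to the index of the key that produced it.
lookup_keys <- function(idx, keys) {
  s <- idx$starts[keys + 1L]
  n <- idx$starts[keys + 2L] - s
  if (sum(n) == 0L) {
    return(list(rec = integer(0), off = integer(0), key_group = integer(0)))
  }
  take <- sequence(n) + rep(s, n)
  list(rec = idx$rec[take], off = idx$off[take],
       key_group = rep(seq_along(keys), n))
}

#' Look up the exact locations of a seed word
#'
#' @param idx a `seed_index`.
#' @param word DNA word of length `idx$word_size`.
#' @return data.frame with columns `seq_id` and `offset` (0-based), sorted;
#'   zero rows when the word does not occur or contains N.
#' @export
seed_lookup <- function(idx, word) {
  stopifnot(inherits(idx, "seed_index"))
  if (nchar(word) != idx$word_size) {
    stop(sprintf("word length %d != index word_size %d", nchar(word),
                 idx$word_size), call. = FALSE)
  }
  key <- encode_word(word)
  if (is.na(key)) {
    return(data.frame(seq_id = character(0), offset = integer(0)))
  }
  hit <- lookup_keys(idx, key)
  data.frame(seq_id = idx$seq_id[hit$rec], offset = hit$off,
             stringsAsFactors = FALSE)
}

#' Summary statistics of a seed index
#'
#' @param idx a `seed_index`.
#' @return list with `word_size`, `keyspace_size`, `n_records`,
#'   `n_locations`, `n_keys_occupied`.
#' @export
index_stats <- function(idx) {
  stopifnot(inherits(idx, "seed_index"))
  idx[c("word_size", "keyspace_size", "n_records", "n_locations",
        "n_keys_occupied")]
}
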