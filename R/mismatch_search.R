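## Gapless approximate search of an L-nt query (default 21) against the
## target space with at most k mismatches (default 3), driven by the seed
## table.
##
## The query is tiled into floor(L / word_size) contiguous word-size parts
## plus a short remainder (21 = 9 + 9 + 3). A hit with m <= k total
## mismatches puts i mismatches in part 1, j in part 2 (i + j <= k), so
## looking up every Hamming variant of each part at distances 0..k and
## joining the resulting locations by their positional relationship (part 2
## must sit exactly word_size downstream of part 1) generates every possible
## alignment. Joined candidates whose per-part distances sum to <= k are
## then verified once at the locus, which settles the remainder and the
## true mismatch count. Targets are indexed sense-strand only; the reverse
## complement of the query is searched to cover the other polarity.

.REC_SHIFT <- 2^32   # candidate locus id = record * 2^32 + start (exact in doubles)

#' Split a query into seed-sized child sequences
#'
#' Tiles the query into contiguous, non-overlapping words of `word_size`
#' plus a possibly empty remainder, e.g. an 18-nt query into two 9-nt
#' children and a 21-nt query into two 9-nt children plus a 3-nt remainder.
#'
#' @param q query DNA string, `nchar(q) >= word_size`.
#' @param word_size seed word length.
#' @return list with `query`, `parts` (data.frame of 0-based `offset` and
#'   `word`) and `remainder` (list of `offset`, `seq`; `seq` is `""` when the
#'   query length is a multiple of `word_size`).
#' @export
split_query <- function(q, word_size = 9L) {
  L <- nchar(q)
  if (L < word_size) {
    stop(sprintf("query length %d < word_size %d", L, word_size), call. = FALSE)
  }
  np <- L %/% word_size
  offs <- (seq_len(np) - 1L) * word_size
  parts <- data.frame(
    offset = offs,
    word = substring(q, offs + 1L, offs + word_size),
    stringsAsFactors = FALSE
  )
  rem_off <- np * word_size
  list(query = q, parts = parts,
       remainder = list(offset = rem_off,
                        seq = if (rem_off < L) substring(q, rem_off + 1L, L) else ""))
}

.check_ts_idx <- function(idx, ts) {
  if (!identical(idx$seq_id, ts$seq_id) || !identical(idx$mode, ts$mode)) {
    stop("seed index was not built over this target space (mode/records differ)",
         call. = FALSE)
  }
}

## Minimal-overhead data.frame constructor for hot paths.
.fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = c(NA_integer_, -length(x[[1L]])))
}

.empty_hits <- function() {
  .fast_df(seq_id = character(0), offset = integer(0),
           mismatches = integer(0), orientation = character(0))
}

ts_codes_cache <- function(ts) {
  env <- attr(ts, "cache")
  if (is.null(env)) new.env(parent = emptyenv()) else env
}

## Candidate loci for one query orientation: per part, look up all Hamming
## variants at exact distances 0..k and convert locations to implied window
## starts; intersect across parts keeping the summed per-part distance.
.seed_candidates <- function(codes, idx, k, L) {
  w <- idx$word_size
  np <- L %/% w
  base_ids <- NULL
  base_dist <- NULL
  for (p in seq_len(np)) {
    off_p <- (p - 1L) * w
    pkey <- 0L
    for (j in seq_len(w)) pkey <- pkey * 4L + codes[off_p + j]
    keys_by_d <- lapply(0:k, function(d) hamming_neighbor_keys(pkey, w, d))
    keys <- unlist(keys_by_d, use.names = FALSE)
    d_of <- rep.int(0:k, lengths(keys_by_d))
    hit <- lookup_keys(idx, keys)
    start <- hit$off - off_p
    ok <- start >= 0L & start + L <= idx$rec_len[hit$rec]
    ids <- hit$rec[ok] * .REC_SHIFT + start[ok]
    dist <- d_of[hit$key_group[ok]]
    if (p == 1L) {
      base_ids <- ids
      base_dist <- dist
    } else {
      m <- match(base_ids, ids)
      keep <- !is.na(m)
      base_ids <- base_ids[keep]
      base_dist <- base_dist[keep] + dist[m[keep]]
    }
    if (length(base_ids) == 0L) break
  }
  keep <- base_dist <= k
  base_ids[keep]
}

## Exact mismatch count of query codes vs one record window; NA (= any N in
## the window) disqualifies the window entirely.
.verify_locus <- function(qcodes, rec_codes, start, L) {
  sub <- rec_codes[(start + 1L):(start + L)]
  if (anyNA(sub)) return(NA_integer_)
  sum(sub != qcodes)
}

#' Seed-table search for all gapless <= k-mismatch alignments
#'
#' Finds every gapless alignment of `q` against the target space with at
#' most `k` mismatches, using the seed index. With
#' `both_query_orientations` (the default, appropriate for siRNA work where
#' a dsRNA yields both polarities) the reverse complement of `q` is searched
#' too and its hits labelled `"revcomp"`.
#'
#' @param q query DNA string (length >= the index word size; 21 for siRNA).
#' @param idx `seed_index` built over `ts`.
#' @param ts the `target_space` the index was built over.
#' @param k maximum mismatches (0..3 is the intended range).
#' @param both_query_orientations search the reverse complement as well.
#' @return data.frame with columns `seq_id`, `offset` (0-based window
#'   start), `mismatches` (the exact count), `orientation`
#'   (`"sense"`/`"revcomp"`). A query containing N yields zero rows with a
#'   warning.
#' @export
seed_search <- function(q, idx, ts, k = 3L, both_query_orientations = TRUE) {
  stopifnot(inherits(idx, "seed_index"))
  .check_ts_idx(idx, ts)
  L <- nchar(q)
  if (L < idx$word_size) {
    stop("query shorter than index word size", call. = FALSE)
  }
  if (grepl("N", q, fixed = TRUE)) {
    warning("query contains N; skipped")
    return(.empty_hits())
  }
  queries <- list(sense = q)
  if (both_query_orientations) queries$revcomp <- reverse_complement(q)

  rec_codes_cache <- ts_codes_cache(ts)
  acc_rec <- acc_off <- acc_mm <- integer(0)
  acc_or <- character(0)
  for (oi in seq_along(queries)) {
    codes <- dna_codes(queries[[oi]])
    ids <- .seed_candidates(codes, idx, as.integer(k), L)
    if (length(ids) == 0L) next
    rec <- as.integer(ids %/% .REC_SHIFT)
    start <- as.integer(ids %% .REC_SHIFT)
    mm <- integer(length(ids))
    for (i in seq_along(ids)) {
      r <- rec[i]
      if (is.null(rec_codes_cache[[paste0("codes_", r)]])) {
        rec_codes_cache[[paste0("codes_", r)]] <- dna_codes(ts$seq[[r]])
      }
      v <- .verify_locus(codes, rec_codes_cache[[paste0("codes_", r)]], start[i], L)
      mm[i] <- if (is.na(v)) NA_integer_ else v
    }
    keep <- !is.na(mm) & mm <= k
    acc_rec <- c(acc_rec, rec[keep])
    acc_off <- c(acc_off, start[keep])
    acc_mm <- c(acc_mm, mm[keep])
    acc_or <- c(acc_or, rep(names(queries)[oi], sum(keep)))
  }
  ord <- order(acc_rec, acc_off, acc_or)
  .fast_df(seq_id = ts$seq_id[acc_rec[ord]], offset = acc_off[ord],
           mismatches = acc_mm[ord], orientation = acc_or[ord])
}

## Concatenated scan subject for the brute-force engine: all records joined
## with N spacers so no window can silently cross a record boundary. N codes
## are replaced by the sentinel 9 (never equal to a query code, so an N is
## always a mismatch); windows containing any N are marked invalid once per
## (space, L). Memoised per target space.
.naive_subject <- function(ts, L) {
  cache <- ts_codes_cache(ts)
  if (is.null(cache$naive_codes)) {
    spacer_len <- 8L
    codes <- lapply(ts$seq, dna_codes)
    nrec <- length(codes)
    joined <- vector("list", 2L * nrec - 1L)
    joined[seq(1L, 2L * nrec - 1L, by = 2L)] <- codes
    if (nrec > 1L) {
      joined[seq(2L, 2L * nrec - 2L, by = 2L)] <-
        rep(list(rep(NA_integer_, spacer_len)), nrec - 1L)
    }
    big <- unlist(joined, use.names = FALSE)
    is_n <- is.na(big)
    big[is_n] <- 9L
    cache$naive_codes <- list(
      big = big,
      ncum = cumsum(is_n),
      rec_start0 = cumsum(c(0L, utils::head(ts$len, -1L) + spacer_len))
    )
  }
  ns <- cache$naive_codes
  vkey <- paste0("naive_valid_", L)
  if (is.null(cache[[vkey]])) {
    n <- length(ns$big) - L + 1L
    st <- seq_len(n)
    # valid = window free of N (which also keeps it inside one record)
    cache[[vkey]] <- (ns$ncum[st + L - 1L] - c(0L, ns$ncum)[st]) == 0L
  }
  list(big = ns$big, rec_start0 = ns$rec_start0, valid = cache[[vkey]])
}

#' Brute-force Hamming-scan search (independent engine)
#'
#' Position-by-position scan of the whole target space: for every window of
#' every record the Hamming distance to the query is computed directly and
#' windows within `k` are reported. Shares no machinery with the seed-table
#' engine, so it serves as its independent cross-check and as the
#' `--engine naive` option. Windows containing N are excluded (an ambiguous
#' base cannot match).
#'
#' @inheritParams seed_search
#' @return data.frame in the same shape as [seed_search()].
#' @export
naive_search <- function(q, ts, k = 3L, both_query_orientations = TRUE) {
  stopifnot(inherits(ts, "target_space"))
  L <- nchar(q)
  if (grepl("N", q, fixed = TRUE)) {
    warning("query contains N; skipped")
    return(.empty_hits())
  }
  queries <- list(sense = q)
  if (both_query_orientations) queries$revcomp <- reverse_complement(q)
  ns <- .naive_subject(ts, L)
  n <- length(ns$big) - L + 1L
  if (n < 1L) return(.empty_hits())

  acc_rec <- acc_off <- acc_mm <- integer(0)
  acc_or <- character(0)
  for (oi in seq_along(queries)) {
    qc <- dna_codes(queries[[oi]])
    sc <- .hamming_scan(ns$big, ns$valid, qc, as.integer(k))
    if (length(sc$pos) == 0L) next
    rec <- findInterval(sc$pos, ns$rec_start0)
    acc_rec <- c(acc_rec, rec)
    acc_off <- c(acc_off, sc$pos - ns$rec_start0[rec])
    acc_mm <- c(acc_mm, sc$mm)
    acc_or <- c(acc_or, rep(names(queries)[oi], length(sc$pos)))
  }
  ord <- order(acc_rec, acc_off, acc_or)
  .fast_df(seq_id = ts$seq_id[acc_rec[ord]], offset = acc_off[ord],
           mismatches = acc_mm[ord], orientation = acc_or[ord])
}
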