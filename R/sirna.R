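## siRNA enumeration, activity scoring, and gene-level off-target mapping.
##
## A long dsRNA spanning a cDNA is diced into ~21-nt siRNAs, so every 21-nt
## window of the mature transcript is a potential silencing unit. Windows
## are scored for likely activity by a named, versioned scoring scheme, and
## each retained siRNA is searched (both orientations) against the target
## space; hits to the source gene itself are dropped.

#' Enumerate all candidate siRNA windows of a cDNA
#'
#' One candidate per start position in `[0, len - L]`; windows containing N
#' are skipped.
#'
#' @param gs a `gene_sequences` object (source gene).
#' @param L siRNA length (default 21).
#' @return data.frame with `source_gene`, `start` (0-based on the cDNA) and
#'   `sequence`; zero rows (with a warning) if the cDNA is shorter than `L`.
#' @export
enumerate_sirnas <- function(gs, L = 21L) {
  stopifnot(inherits(gs, "gene_sequences"))
  n <- nchar(gs$mature) - L + 1L
  if (n < 1L) {
    warning(sprintf("cDNA of '%s' (%d nt) is shorter than L=%d", gs$gene_id,
                    nchar(gs$mature), L))
    return(data.frame(source_gene = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  starts <- 0:(n - 1L)
  seqs <- substring(gs$mature, starts + 1L, starts + L)
  ok <- !grepl("N", seqs, fixed = TRUE)
  data.frame(source_gene = gs$gene_id, start = starts[ok], sequence = seqs[ok],
             stringsAsFactors = FALSE)
}

#' Named siRNA activity-scoring schemes
#'
#' `"none"` passes every candidate (score 0, threshold 0); use it when cot
#' statistics must not be thinned by the activity filter. `"default-v1"` is
#' this package's documented default rule set: one point each for (a) GC
#' fraction in `[0.30, 0.60]`, (b) no homopolymer run of 5 or more, and
#' (c) A or T at sense-strand position 19 of the 21-mer (a thermodynamic
#' asymmetry proxy); a candidate passes with at least 2 of 3 points. The
#' scheme slot is pluggable so an alternative rule set can be swapped in
#' without touching the pipeline.
#'
#' @param name scheme name.
#' @return list with `name`, `version`, `threshold` and scoring function
#'   `fn(sequences) -> numeric scores`.
#' @export
scoring_scheme <- function(name = c("default-v1", "none")) {
  name <- match.arg(name)
  if (name == "none") {
    return(list(name = "none", version = "1", threshold = 0,
                fn = function(seqs) rep(0, length(seqs))))
  }
  list(
    name = "default-v1", version = "1", threshold = 2,
    fn = function(seqs) {
      n <- nchar(seqs)
      gc <- (nchar(gsub("[^GC]", "", seqs))) / pmax(n, 1L)
      p_gc <- as.numeric(gc >= 0.30 & gc <= 0.60)
      p_run <- as.numeric(!grepl("A{5,}|C{5,}|G{5,}|T{5,}", seqs))
      p_asym <- as.numeric(substring(seqs, 19L, 19L) %in% c("A", "T"))
      p_gc + p_run + p_asym
    }
  )
}

#' Score siRNA candidates
#'
#' @param cands data.frame from [enumerate_sirnas()].
#' @param scheme a scheme from [scoring_scheme()], or a scheme name.
#' @return `cands` with `score` and `passed_filter` columns added.
#' @export
score_sirnas <- function(cands, scheme = "default-v1") {
  if (is.character(scheme)) scheme <- scoring_scheme(scheme)
  cands$score <- scheme$fn(cands$sequence)
  cands$passed_filter <- cands$score >= scheme$threshold
  cands
}

## Region label of a hit window: in premrna mode a window is "exon" only if
## every aligned position is exon-labelled; a window touching an intron
## (including exon/intron straddlers) is "intron", because no mature RNA
## contains it. Mature-mode records are exonic by construction.
.hit_region <- function(ts, rec, offset, L) {
  if (ts$mode == "mature") return(rep("exon", length(rec)))
  vapply(seq_along(rec), function(i) {
    lab <- ts$region[[rec[i]]][(offset[i] + 1L):(offset[i] + L)]
    if (all(lab == "exon")) "exon" else "intron"
  }, character(1))
}

.empty_offtargets <- function() {
  data.frame(source_gene = character(0), sirna_start = integer(0),
             sequence = character(0), score = numeric(0),
             target_gene = character(0), seq_id = character(0),
             offset = integer(0), mismatches = integer(0),
             orientation = character(0), region = character(0),
             stringsAsFactors = FALSE)
}

#' Map off-target genes for a set of siRNA candidates
#'
#' Searches every candidate that passed the activity filter against the
#' target space (both query orientations), annotates each hit with the
#' target gene and its exon/intron region, and removes hits to the source
#' gene itself.
#'
#' @param cands scored candidates from [score_sirnas()].
#' @param idx `seed_index` over `ts`.
#' @param ts the `target_space` (its mode decides premrna vs mature
#'   semantics).
#' @param k maximum mismatches (default 3).
#' @param L siRNA length (default 21).
#' @param engine `"seeded"` (the seed-table algorithm) or `"naive"` (the
#'   brute-force cross-check engine).
#' @return data.frame of off-target hits: `source_gene`, `sirna_start`
#'   (0-based), `sequence`, `score`, `target_gene`, `seq_id`, `offset`
#'   (0-based), `mismatches`, `orientation`, `region`.
#' @export
map_offtargets <- function(cands, idx = NULL, ts, k = 3L, L = 21L,
                           engine = c("seeded", "naive")) {
  engine <- match.arg(engine)
  stopifnot(inherits(ts, "target_space"))
  if (engine == "seeded") {
    if (is.null(idx)) stop("seeded engine needs a seed_index", call. = FALSE)
    .check_ts_idx(idx, ts)
  }
  if (is.null(cands$passed_filter)) cands$passed_filter <- TRUE
  if (is.null(cands$score)) cands$score <- 0
  use <- which(cands$passed_filter)
  out <- vector("list", length(use))
  gene_of <- stats::setNames(ts$gene_id, ts$seq_id)
  for (ii in seq_along(use)) {
    i <- use[ii]
    hits <- if (engine == "seeded") {
      seed_search(cands$sequence[i], idx, ts, k = k,
                  both_query_orientations = TRUE)
    } else {
      naive_search(cands$sequence[i], ts, k = k,
                   both_query_orientations = TRUE)
    }
    if (nrow(hits) == 0L) next
    tg <- unname(gene_of[hits$seq_id])
    keep <- tg != cands$source_gene[i]
    if (!any(keep)) next
    hits <- hits[keep, , drop = FALSE]
    rec <- match(hits$seq_id, ts$seq_id)
    out[[ii]] <- data.frame(
      source_gene = cands$source_gene[i], sirna_start = cands$start[i],
      sequence = cands$sequence[i], score = cands$score[i],
      target_gene = tg[keep], seq_id = hits$seq_id, offset = hits$offset,
      mismatches = hits$mismatches, orientation = hits$orientation,
      region = .hit_region(ts, rec, hits$offset, L),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_offtargets())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop off-target hits that touch intron sequence
#'
#' Keeps only hits whose full aligned window lies in exon-labelled
#' positions; hits inside an intron, or straddling an exon/intron boundary
#' (a window no mature RNA contains), are removed. Meaningful for
#' premrna-mode hits; mature-mode hits are all exonic already.
#'
#' @param hits data.frame from [map_offtargets()].
#' @return the exon-only subset.
#' @export
filter_intron_hits <- function(hits) {
  res <- hits[hits$region == "exon", , drop = FALSE]
  rownames(res) <- NULL
  res
}
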