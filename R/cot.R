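## Common-off-target (cot) analysis and dsRNA region design.
##
## A cot-group is 2 or more siRNAs derived from one source gene that map to
## the same off-target gene. If two non-overlapping dsRNAs each contain a
## member of one cot-group, both reagents can silence that off-target and a
## shared phenotype can be misread as on-target; the design step therefore
## looks for region pairs whose off-target gene sets are disjoint.

#' Form cot-groups from an off-target hit table
#'
#' Groups hits by (source gene, off-target gene); groups with at least two
#' distinct siRNA start positions are cot-groups, singletons are discarded.
#' Orientation and mismatch count do not affect membership; duplicate
#' (siRNA, target gene) pairs from multiple loci collapse.
#'
#' @param hits data.frame from [map_offtargets()] (gene-aggregated).
#' @return data.frame with `source_gene`, `offtarget_gene`, `size` and a
#'   list-column `members` of sorted 0-based siRNA starts.
#' @export
form_cot_groups <- function(hits) {
  empty <- data.frame(source_gene = character(0), offtarget_gene = character(0),
                      size = integer(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(hits) == 0L) return(empty)
  u <- unique(hits[, c("source_gene", "target_gene", "sirna_start")])
  key <- paste(u$source_gene, u$target_gene, sep = "\r")
  members <- lapply(split(u$sirna_start, key), function(s) sort(unique(s)))
  size <- lengths(members)
  keep <- size >= 2L
  if (!any(keep)) return(empty)
  members <- members[keep]
  parts <- strsplit(names(members), "\r", fixed = TRUE)
  out <- data.frame(
    source_gene = vapply(parts, `[`, character(1), 1L),
    offtarget_gene = vapply(parts, `[`, character(1), 2L),
    size = unname(size[keep]),
    stringsAsFactors = FALSE
  )
  out$members <- unname(members)
  ord <- order(out$source_gene, out$offtarget_gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene cot statistics
#'
#' Coverage is the fraction of the gene written as a percentage:
#' `100 * (total members across groups) * L / gene_length`. A single siRNA
#' belonging to several cot-groups is counted once per group, so coverage
#' can exceed 100 for large genes.
#'
#' @param groups cot-groups of a single source gene ([form_cot_groups()]).
#' @param gene_length length of the source cDNA (nt).
#' @param L siRNA length (default 21).
#' @return one-row data.frame: `n_cot_groups`, `max_group_size`,
#'   `coverage_percent`, `gene_length`.
#' @export
cot_stats <- function(groups, gene_length, L = 21L) {
  if (gene_length < L) {
    stop(sprintf("gene_length %d < siRNA length %d", gene_length, L),
         call. = FALSE)
  }
  if (nrow(groups) > 0L && length(unique(groups$source_gene)) > 1L) {
    stop("cot_stats() expects groups of a single source gene", call. = FALSE)
  }
  data.frame(
    n_cot_groups = nrow(groups),
    max_group_size = if (nrow(groups) == 0L) 0L else max(groups$size),
    coverage_percent = if (nrow(groups) == 0L) 0 else
      100 * sum(groups$size) * L / gene_length,
    gene_length = as.integer(gene_length)
  )
}

## Pair constraints implied by the groups: an interval that fully contains
## two member sites of one group is dirty. Only consecutive members matter:
## containing two non-adjacent members forces containment of the ones
## between them. Constraint = (s1, end2) meaning intervals [a, b) with
## a <= s1 and b >= end2 are forbidden.
.pair_constraints <- function(groups, L) {
  if (nrow(groups) == 0L) {
    return(cbind(s1 = integer(0), end2 = integer(0)))
  }
  cons <- lapply(groups$members, function(m) {
    if (length(m) < 2L) return(NULL)
    cbind(s1 = m[-length(m)], end2 = m[-1L] + L)
  })
  do.call(rbind, cons)
}

#' Maximal clean ("green") regions of a cDNA
#'
#' Returns the maximal intervals of the cDNA that do not fully contain two
#' member sites (each site being `[start, start + L)`) of any single
#' cot-group — the regions from which a single dsRNA can be drawn without
#' incorporating a shared off-target pair. Optionally intersected with the
#' complement of a UTR mask.
#'
#' @param groups cot-groups of one source gene.
#' @param gene_length cDNA length.
#' @param L siRNA length.
#' @param utr_mask optional 2-column matrix of 0-based half-open intervals
#'   to exclude (e.g. `gene_sequences$utr_mature`).
#' @return 2-column matrix (`start`, `end`) of 0-based half-open intervals,
#'   sorted; a single `[0, gene_length)` row when there are no constraints.
#' @export
clean_regions <- function(groups, gene_length, L = 21L, utr_mask = NULL) {
  cons <- .pair_constraints(groups, L)
  cons <- cons[cons[, "end2"] <= gene_length & cons[, "s1"] >= 0L, ,
               drop = FALSE]
  if (nrow(cons) == 0L) {
    regs <- cbind(start = 0L, end = as.integer(gene_length))
  } else {
    ord <- order(cons[, "s1"])
    s1 <- cons[ord, "s1"]
    e2 <- cons[ord, "end2"]
    suff_min <- rev(cummin(rev(e2)))
    cand_a <- sort(unique(c(0L, s1 + 1L)))
    cand_a <- cand_a[cand_a < gene_length]
    starts <- ends <- integer(0)
    best_end <- -1L
    for (a in cand_a) {
      j <- findInterval(a - 0.5, s1) + 1L    # first constraint with s1 >= a
      b <- if (j > length(s1)) gene_length else min(gene_length, suff_min[j] - 1L)
      if (b > a && b > best_end) {
        starts <- c(starts, a); ends <- c(ends, b)
        best_end <- b
      }
    }
    regs <- cbind(start = starts, end = ends)
  }
  if (!is.null(utr_mask) && nrow(utr_mask) > 0L) {
    ir <- IRanges::IRanges(start = regs[, 1L] + 1L, end = regs[, 2L])
    mask <- IRanges::IRanges(start = utr_mask[, 1L] + 1L, end = utr_mask[, 2L])
    left <- IRanges::setdiff(ir, mask)
    regs <- cbind(start = IRanges::start(left) - 1L, end = IRanges::end(left))
  }
  regs
}

## Off-target gene sets of the siRNA sites wholly inside [a, b).
.region_gene_set <- function(start_gene, a, b, L) {
  idx <- start_gene$start >= a & start_gene$start + L <= b
  unique(start_gene$gene[idx])
}

#' Design pairs of dsRNA regions with no shared off-target gene
#'
#' Searches for up to `n_choices` pairs of non-overlapping cDNA regions,
#' each within `[min_len, max_len]`, such that the off-target gene sets of
#' the siRNA sites wholly contained in region 1 and region 2 are disjoint.
#' The hit table should come from scoring scheme `"none"` so the guarantee
#' does not depend on the activity filter being right. A site partially
#' overlapping a region boundary is treated as outside the region (a
#' truncated 21-mer cannot arise from that amplicon). Candidate regions are
#' laid on a 21-nt grid; pairs are ranked by descending combined length,
#' ties broken by leftmost region 1 then region 2.
#'
#' @param gene a `gene_sequences` object (the source gene).
#' @param hits off-target hit table for this gene (scheme `"none"`).
#' @param min_len,max_len dsRNA length bounds (defaults 300 and 800 nt).
#' @param avoid_utr exclude candidate regions overlapping mature UTRs.
#' @param n_choices maximum number of pairs to return.
#' @param L siRNA length.
#' @return list of class `dsrna_design`: `pairs` (data.frame of 1 row per
#'   emitted pair with 0-based half-open region coordinates and combined
#'   length), `feasible` flag, and for the infeasible case
#'   `blocking_genes`, the off-target genes shared by every examined
#'   candidate pair, most frequent first.
#' @export
design_dsrna_pairs <- function(gene, hits, min_len = 300L, max_len = 800L,
                               avoid_utr = FALSE, n_choices = 5L, L = 21L) {
  stopifnot(inherits(gene, "gene_sequences"), min_len <= max_len)
  glen <- gene$gene_length
  if (glen < 2L * min_len) {
    stop(sprintf("cDNA of '%s' (%d nt) is shorter than 2 * min_len = %d",
                 gene$gene_id, glen, 2L * min_len), call. = FALSE)
  }
  sg <- if (nrow(hits) == 0L) {
    data.frame(start = integer(0), gene = character(0))
  } else {
    u <- unique(hits[, c("sirna_start", "target_gene")])
    data.frame(start = u$sirna_start, gene = u$target_gene,
               stringsAsFactors = FALSE)
  }
  utr <- if (avoid_utr) gene$utr_mature else NULL
  grid <- unique(c(seq(0L, glen - min_len, by = L), glen - min_len))

  cand <- expand.grid(a1 = grid, a2 = grid)
  cand <- cand[cand$a2 >= cand$a1 + min_len, , drop = FALSE]
  if (nrow(cand) > 0L) {
    cand$len1 <- pmin(max_len, cand$a2 - cand$a1)
    cand$len2 <- pmin(max_len, glen - cand$a2)
    cand <- cand[cand$len2 >= min_len, , drop = FALSE]
  }
  if (!is.null(utr) && nrow(utr) > 0L && nrow(cand) > 0L) {
    no_utr <- function(a, b) {
      !any(a < utr[, 2L] & utr[, 1L] < b)
    }
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      no_utr(cand$a1[i], cand$a1[i] + cand$len1[i]) &&
        no_utr(cand$a2[i], cand$a2[i] + cand$len2[i])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(structure(list(
      gene = gene$gene_id, feasible = FALSE,
      pairs = .empty_pairs(), blocking_genes = character(0),
      options = list(min_len = min_len, max_len = max_len,
                     avoid_utr = avoid_utr, n_choices = n_choices)
    ), class = "dsrna_design"))
  }
  cand <- cand[order(-(cand$len1 + cand$len2), cand$a1, cand$a2), ,
               drop = FALSE]

  pairs <- list()
  shared_all <- NULL
  shared_tally <- character(0)
  for (i in seq_len(nrow(cand))) {
    g1 <- .region_gene_set(sg, cand$a1[i], cand$a1[i] + cand$len1[i], L)
    g2 <- .region_gene_set(sg, cand$a2[i], cand$a2[i] + cand$len2[i], L)
    shared <- intersect(g1, g2)
    if (length(shared) == 0L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        region1_start = cand$a1[i], region1_end = cand$a1[i] + cand$len1[i],
        region2_start = cand$a2[i], region2_end = cand$a2[i] + cand$len2[i],
        combined_length = cand$len1[i] + cand$len2[i]
      )
      if (length(pairs) >= n_choices) break
    } else {
      shared_all <- if (is.null(shared_all)) shared else
        intersect(shared_all, shared)
      shared_tally <- c(shared_tally, shared)
    }
  }
  feasible <- length(pairs) > 0L
  blocking <- character(0)
  if (!feasible) {
    blocking <- if (length(shared_all) > 0L) shared_all else
      names(sort(table(shared_tally), decreasing = TRUE))
  }
  structure(list(
    gene = gene$gene_id, feasible = feasible,
    pairs = if (feasible) do.call(rbind, pairs) else .empty_pairs(),
    blocking_genes = blocking,
    options = list(min_len = min_len, max_len = max_len,
                   avoid_utr = avoid_utr, n_choices = n_choices)
  ), class = "dsrna_design")
}

.empty_pairs <- function() {
  data.frame(region1_start = integer(0), region1_end = integer(0),
             region2_start = integer(0), region2_end = integer(0),
             combined_length = integer(0))
}

#' @export
print.dsrna_design <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<dsrna_design> %s: %d clean pair(s)\n", x$gene, nrow(x$pairs)))
  } else {
    cat(sprintf("<dsrna_design> %s: no clean pair; blocking gene(s): %s\n",
                x$gene, paste(x$blocking_genes, collapse = ", ")))
  }
  invisible(x)
}

#' Expected number of random <= k-mismatch matches
#'
#' Closed-form expectation of the number of gapless alignments of one
#' random L-mer against an i.i.d. random genome:
#' `S * sum_{i=0..k} choose(L, i) * 3^i / 4^L`, where `S` is the number of
#' genomic window positions (doubled when both strands are searched). An
#' approximation that ignores edge effects and the dependence between
#' overlapping windows.
#'
#' @param L query length.
#' @param k maximum mismatches.
#' @param genome_size genome length (nt).
#' @param both_strands double the searched space.
#' @return the expected match count.
#' @export
expected_random_matches <- function(L, k, genome_size, both_strands = FALSE) {
  stopifnot(L >= 1, k >= 0, k <= L)
  S <- genome_size * (if (both_strands) 2 else 1)
  S * hamming_ball_size(L, k) / 4^L
}
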