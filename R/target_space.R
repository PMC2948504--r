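## Target spaces: the indexed collection of per-gene RNA sequences.
##
## premrna mode holds one record per gene (the unspliced, strand-corrected
## gene span) with an exon/intron region map; mature mode holds the spliced
## transcript chosen for each gene with a UTR5/CDS/UTR3 map. Only the sense
## strand of each record is stored and indexed; queries are searched in both
## orientations instead.

#' Build a target space from gene models
#'
#' @param models named list of gene models from [load_gene_models()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param mode `"premrna"` (unspliced gene spans) or `"mature"` (spliced
#'   transcripts).
#' @param transcripts optional named character vector `gene_id -> transcript_id`
#'   overriding the longest-transcript default.
#' @return an object of class `target_space`.
#' @export
target_space <- function(models, genome, mode = c("premrna", "mature"),
                         transcripts = NULL) {
  mode <- match.arg(mode)
  seqs <- lapply(models, function(m) {
    extract_sequences(m, genome, transcript = transcripts[[m$gene_id]])
  })
  if (mode == "premrna") {
    recs <- lapply(seqs, function(s) {
      list(seq_id = s$gene_id, gene_id = s$gene_id, seq = s$premrna,
           region = s$premrna_region)
    })
  } else {
    recs <- lapply(seqs, function(s) {
      list(seq_id = s$transcript_id, gene_id = s$gene_id, seq = s$mature,
           region = s$mature_region)
    })
  }
  new_target_space(
    mode = mode,
    seq_id = vapply(recs, `[[`, character(1), "seq_id"),
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    seq = vapply(recs, `[[`, character(1), "seq"),
    region = lapply(recs, `[[`, "region")
  )
}

new_target_space <- function(mode, seq_id, gene_id, seq, region) {
  stopifnot(length(seq_id) == length(gene_id), length(seq_id) == length(seq),
            !anyDuplicated(seq_id))
  ts <- structure(
    list(mode = mode,
         seq_id = unname(seq_id), gene_id = unname(gene_id),
         seq = unname(seq), region = unname(region),
         len = nchar(unname(seq))),
    class = "target_space"
  )
  # per-record derived objects (base codes, DNAStringSet) are memoised here;
  # an environment survives copying of the list
  attr(ts, "cache") <- new.env(parent = emptyenv())
  ts
}

#' @export
print.target_space <- function(x, ...) {
  cat(sprintf("<target_space> mode=%s, %d record(s), %d nt total\n",
              x$mode, length(x$seq_id), sum(x$len)))
  invisible(x)
}

#' Load a pre-built transcriptome bundle
#'
#' Alternative input to FASTA+GFF3: two FASTA files of per-gene sequences
#' (mature and pre-mRNA) plus a TSV gene map with columns
#' `gene_id`, `transcript_id`, `n_exons`, `utr5_len`, `utr3_len`. Mature
#' record IDs may be `gene_id` or `gene_id|transcript_id`. Region maps are
#' reconstructed from the UTR lengths (mature) and left unlabelled
#' (all-exon) for pre-mRNA records, since the bundle does not carry intron
#' intervals.
#'
#' @param mature_fasta,premrna_fasta FASTA paths.
#' @param gene_map_tsv TSV path.
#' @param mode which target space to assemble.
#' @return a `target_space`.
#' @export
load_bundle <- function(mature_fasta, premrna_fasta, gene_map_tsv,
                        mode = c("premrna", "mature")) {
  mode <- match.arg(mode)
  map <- utils::read.delim(gene_map_tsv, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "n_exons", "utr5_len", "utr3_len")
  if (!all(need %in% names(map))) {
    stop("gene map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fa <- load_genome(if (mode == "mature") mature_fasta else premrna_fasta)
  rec_gene <- sub("\\|.*$", "", names(fa))
  keep <- rec_gene %in% map$gene_id
  if (!any(keep)) stop("no bundle records match the gene map", call. = FALSE)
  fa <- fa[keep]; rec_gene <- rec_gene[keep]
  seqs <- as.character(fa)
  if (mode == "mature") {
    m <- map[match(rec_gene, map$gene_id), ]
    region <- lapply(seq_along(seqs), function(i) {
      n <- nchar(seqs[[i]])
      r <- rep("CDS", n)
      u5 <- min(m$utr5_len[i], n); u3 <- min(m$utr3_len[i], n)
      if (u5 > 0L) r[seq_len(u5)] <- "UTR5"
      if (u3 > 0L) r[(n - u3 + 1L):n] <- "UTR3"
      r
    })
    seq_id <- ifelse(grepl("\\|", names(fa)), sub("^.*\\|", "", names(fa)),
                     m$transcript_id)
  } else {
    region <- lapply(nchar(seqs), function(n) rep("exon", n))
    seq_id <- rec_gene
  }
  new_target_space(mode = mode, seq_id = seq_id, gene_id = rec_gene,
                   seq = seqs, region = region)
}
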