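## Gene models and sequence extraction.
##
## Coordinates are 0-based half-open everywhere inside the package (GFF3's
## 1-based closed intervals are converted on entry); user-facing reports are
## 1-based. A gene model carries its transcripts; each transcript carries
## genomic exon and UTR intervals. Sequences are produced strand-corrected
## (5'->3'): `premrna` is the full unspliced gene span, `mature` the spliced
## transcript, and per-position region maps label premrna positions as
## exon/intron and mature positions as UTR5/CDS/UTR3.

new_gene_model <- function(gene_id, chrom, strand, start, end, transcripts) {
  stopifnot(strand %in% c("+", "-"), end > start)
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = as.integer(start), end = as.integer(end),
         transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$start + 1L, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

.gff_first_parent <- function(parent) {
  if (length(parent) == 0L) NA_character_ else parent[[1L]]
}

#' Load gene models from a genome FASTA and GFF3 annotation
#'
#' Reads gene / mRNA / exon / five_prime_UTR / three_prime_UTR features and
#' assembles one gene model per gene, with intervals converted to 0-based
#' half-open coordinates. FASTA record names must cover every seqid used in
#' the GFF3.
#'
#' @param fasta_path path to the genome FASTA.
#' @param gff_path path to the GFF3 annotation.
#' @return named list of gene models (names are gene IDs), in GFF order.
#' @export
load_gene_models <- function(fasta_path, gff_path) {
  genome <- load_genome(fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  missing_seq <- setdiff(unique(seqid), names(genome))
  if (length(missing_seq) > 0L) {
    stop("GFF3 seqid(s) absent from FASTA: ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, .gff_first_parent, character(1))
  } else rep(NA_character_, length(gr))
  st0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  en0 <- GenomicRanges::end(gr)
  strand_chr <- as.character(GenomicRanges::strand(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  gene_ids <- ids[is_gene]
  if (anyNA(gene_ids)) stop("gene feature without ID attribute", call. = FALSE)

  gene_rows <- which(is_gene)
  names(gene_rows) <- gene_ids
  tx_rows <- which(is_tx)
  tx_ids <- ids[tx_rows]
  if (anyNA(tx_ids)) stop("mRNA feature without ID attribute", call. = FALSE)
  tx_parent <- parents[tx_rows]
  bad_tx <- which(is.na(tx_parent) | !(tx_parent %in% gene_ids))
  if (length(bad_tx) > 0L) {
    stop(sprintf("mRNA '%s' has no Parent gene in the GFF3", tx_ids[bad_tx[1L]]),
         call. = FALSE)
  }
  names(tx_rows) <- tx_ids

  part_types <- c("exon", "five_prime_UTR", "three_prime_UTR")
  part_rows <- which(type %in% part_types)
  for (r in part_rows) {
    p <- parents[r]
    if (is.na(p) || !(p %in% tx_ids)) {
      stop(sprintf("%s feature at %s:%d-%d has Parent '%s' which is not an mRNA",
                   type[r], seqid[r], st0[r] + 1L, en0[r],
                   ifelse(is.na(parents[r]), "<missing>", parents[r])),
           call. = FALSE)
    }
  }

  models <- vector("list", length(gene_rows))
  names(models) <- gene_ids
  for (gid in gene_ids) {
    g <- gene_rows[[gid]]
    g_start <- st0[g]; g_end <- en0[g]
    this_tx <- tx_ids[tx_parent == gid]
    transcripts <- vector("list", length(this_tx))
    names(transcripts) <- this_tx
    for (tid in this_tx) {
      take <- function(what) {
        r <- part_rows[type[part_rows] == what & parents[part_rows] == tid]
        if (length(r) == 0L) {
          return(matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("start", "end"))))
        }
        m <- cbind(start = st0[r], end = en0[r])
        m[order(m[, 1L]), , drop = FALSE]
      }
      exons <- take("exon")
      if (nrow(exons) == 0L) {
        stop(sprintf("mRNA '%s' has no exon features", tid), call. = FALSE)
      }
      if (any(exons[, "start"] < g_start) || any(exons[, "end"] > g_end)) {
        stop(sprintf("exon of mRNA '%s' lies outside gene '%s' span", tid, gid),
             call. = FALSE)
      }
      if (nrow(exons) > 1L &&
          any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
        stop(sprintf("overlapping exons in mRNA '%s'", tid), call. = FALSE)
      }
      utr5 <- take("five_prime_UTR")
      utr3 <- take("three_prime_UTR")
      for (u in list(utr5, utr3)) {
        if (nrow(u) > 0L) {
          inside <- vapply(seq_len(nrow(u)), function(i) {
            any(u[i, 1L] >= exons[, 1L] & u[i, 2L] <= exons[, 2L])
          }, logical(1))
          if (!all(inside)) {
            stop(sprintf("UTR of mRNA '%s' not contained in an exon", tid),
                 call. = FALSE)
          }
        }
      }
      transcripts[[tid]] <- list(transcript_id = tid, exons = exons,
                                 utr5 = utr5, utr3 = utr3)
    }
    models[[gid]] <- new_gene_model(
      gene_id = gid, chrom = seqid[g], strand = strand_chr[g],
      start = g_start, end = g_end, transcripts = transcripts
    )
  }
  models
}

#' Read a genome FASTA into a DNAStringSet
#'
#' Record names are truncated at the first whitespace.
#'
#' @param fasta_path path to a (multi-)FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
load_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  if (length(genome) == 0L) stop("empty FASTA: ", fasta_path, call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

## Transform a genomic 0-based half-open interval into gene-local
## strand-corrected coordinates (position 0 = transcription start).
.to_local <- function(ivl, g_start, g_end, strand) {
  if (strand == "+") {
    cbind(start = ivl[, 1L] - g_start, end = ivl[, 2L] - g_start)
  } else {
    m <- cbind(start = g_end - ivl[, 2L], end = g_end - ivl[, 1L])
    m[order(m[, 1L]), , drop = FALSE]
  }
}

## Pick the analysed transcript: an explicit ID, otherwise the longest
## mature transcript (first wins on ties).
choose_transcript <- function(gene, transcript = NULL) {
  if (!is.null(transcript)) {
    tx <- gene$transcripts[[transcript]]
    if (is.null(tx)) {
      stop(sprintf("gene '%s' has no transcript '%s' (has: %s)", gene$gene_id,
                   transcript, paste(names(gene$transcripts), collapse = ", ")),
           call. = FALSE)
    }
    return(tx)
  }
  len <- vapply(gene$transcripts,
                function(t) sum(t$exons[, 2L] - t$exons[, 1L]), numeric(1))
  gene$transcripts[[which.max(len)]]
}

#' Extract mature and pre-mRNA sequences for one gene
#'
#' Produces the strand-corrected unspliced gene-span sequence (`premrna`),
#' the spliced transcript sequence (`mature`), and per-position region maps:
#' exon/intron over the pre-mRNA and UTR5/CDS/UTR3 over the mature sequence.
#' For multi-transcript genes the longest mature transcript is analysed
#' unless `transcript` names one.
#'
#' @param gene a gene model from [load_gene_models()].
#' @param genome a [Biostrings::DNAStringSet] holding the gene's chromosome.
#' @param transcript optional transcript ID.
#' @return an object of class `gene_sequences`.
#' @export
extract_sequences <- function(gene, genome, transcript = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  chrom <- genome[[gene$chrom]]
  if (is.null(chrom)) {
    stop(sprintf("chromosome '%s' not in genome", gene$chrom), call. = FALSE)
  }
  if (gene$start < 0L || gene$end > length(chrom)) {
    stop(sprintf("gene '%s' span [%d,%d) exceeds contig '%s' length %d",
                 gene$gene_id, gene$start, gene$end, gene$chrom, length(chrom)),
         call. = FALSE)
  }
  span <- Biostrings::subseq(chrom, start = gene$start + 1L, end = gene$end)
  if (gene$strand == "-") span <- Biostrings::reverseComplement(span)
  premrna <- as.character(span)
  if (grepl("[^ACGTN]", premrna)) {
    stop(sprintf("gene '%s' sequence contains characters outside {A,C,G,T,N}",
                 gene$gene_id), call. = FALSE)
  }
  tx <- choose_transcript(gene, transcript)
  exons_local <- .to_local(tx$exons, gene$start, gene$end, gene$strand)
  span_len <- gene$end - gene$start

  premrna_region <- rep("intron", span_len)
  for (i in seq_len(nrow(exons_local))) {
    premrna_region[(exons_local[i, 1L] + 1L):exons_local[i, 2L]] <- "exon"
  }
  mature <- paste(substring(premrna, exons_local[, 1L] + 1L, exons_local[, 2L]),
                  collapse = "")
  mature_len <- nchar(mature)

  cum_before <- c(0L, cumsum(exons_local[, 2L] - exons_local[, 1L]))
  local_to_mature <- function(ivl_local) {
    if (nrow(ivl_local) == 0L) {
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    out <- matrix(0L, nrow(ivl_local), 2L,
                  dimnames = list(NULL, c("start", "end")))
    for (i in seq_len(nrow(ivl_local))) {
      e <- which(ivl_local[i, 1L] >= exons_local[, 1L] &
                 ivl_local[i, 2L] <= exons_local[, 2L])[1L]
      if (is.na(e)) {
        stop("UTR interval not contained in a single exon", call. = FALSE)
      }
      out[i, ] <- cum_before[e] + (ivl_local[i, ] - exons_local[e, 1L])
    }
    out[order(out[, 1L]), , drop = FALSE]
  }
  utr5_mat <- local_to_mature(.to_local(tx$utr5, gene$start, gene$end, gene$strand))
  utr3_mat <- local_to_mature(.to_local(tx$utr3, gene$start, gene$end, gene$strand))

  mature_region <- rep("CDS", mature_len)
  for (i in seq_len(nrow(utr5_mat))) {
    mature_region[(utr5_mat[i, 1L] + 1L):utr5_mat[i, 2L]] <- "UTR5"
  }
  for (i in seq_len(nrow(utr3_mat))) {
    mature_region[(utr3_mat[i, 1L] + 1L):utr3_mat[i, 2L]] <- "UTR3"
  }

  structure(
    list(gene_id = gene$gene_id, transcript_id = tx$transcript_id,
         strand = gene$strand, mature = mature, premrna = premrna,
         premrna_region = premrna_region, mature_region = mature_region,
         exons_local = exons_local,
         utr_mature = rbind(utr5_mat, utr3_mat),
         gene_length = mature_len, span_length = span_len),
    class = "gene_sequences"
  )
}

#' @export
print.gene_sequences <- function(x, ...) {
  cat(sprintf("<gene_sequences> %s (%s): mature %d nt, pre-mRNA %d nt, %d exon(s)\n",
              x$gene_id, x$transcript_id, x$gene_length, x$span_length,
              nrow(x$exons_local)))
  invisible(x)
}
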