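# Shared helpers: in-code toy genomes, minimal objects, small oracles.

write_toy <- function(contigs, features) {
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  writeLines(as.vector(rbind(paste0(">", names(contigs)), unname(contigs))), fa)
  writeLines(c("##gff-version 3", features), gff)
  list(fasta = fa, gff = gff)
}

# a single-exon gene_sequences stub for siRNA-level tests
make_gs <- function(mature, gene_id = "G1") {
  n <- nchar(mature)
  structure(list(
    gene_id = gene_id, transcript_id = paste0(gene_id, "-RA"), strand = "+",
    mature = mature, premrna = mature,
    premrna_region = rep("exon", n), mature_region = rep("CDS", n),
    exons_local = cbind(start = 0L, end = n),
    utr_mature = cbind(start = integer(0), end = integer(0)),
    gene_length = n, span_length = n
  ), class = "gene_sequences")
}

# target space straight from named sequences (all-exon region maps unless given)
make_ts <- function(seqs, mode = "premrna", gene_ids = NULL, regions = NULL) {
  if (is.null(gene_ids)) gene_ids <- names(seqs)
  if (is.null(regions)) {
    regions <- lapply(nchar(seqs), function(n) {
      rep(if (mode == "mature") "CDS" else "exon", n)
    })
  }
  cotscan:::new_target_space(mode = mode, seq_id = names(seqs),
                             gene_id = gene_ids, seq = unname(seqs),
                             region = regions)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

hit_key <- function(h) {
  paste(h$seq_id, h$offset, h$mismatches, h$orientation, sep = "/")
}

# generate fixture + parse it back
fixture_env <- function(spec, dir = tempfile("fix")) {
  fix <- generate_fixture(spec, dir)
  models <- load_gene_models(fix$fasta, fix$gff)
  genome <- load_genome(fix$fasta)
  list(fix = fix, models = models, genome = genome)
}
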