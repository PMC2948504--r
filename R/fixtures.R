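## Deterministic synthetic genomes with planted off-target structure.
##
## Backgrounds are i.i.d. random sequence (the randomized-genome assumption
## behind the analytic expectation), one contig per gene with short flanks.
## A plant copies a 21-nt window of a source gene's cDNA, mutates it to an
## exact Hamming distance, optionally reverse-complements it, and writes it
## into a chosen region (exon / intron / utr) of a target gene — giving a
## ground-truth table against which pipeline recovery is asserted. Identical
## specs (including seed) produce byte-identical files.

#' Specification of a synthetic fixture genome
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_genes number of genes (one contig each).
#' @param gene_length_range range of mature cDNA lengths (nt).
#' @param gene_lengths optional explicit per-gene cDNA lengths (recycled to
#'   `n_genes`); overrides `gene_length_range`.
#' @param exons_per_gene_range range of exon counts.
#' @param intron_length_range range of intron lengths (nt).
#' @param utr_lengths pair `(utr5, utr3)` of UTR lengths on the mature
#'   transcript (clamped to fit the terminal exons).
#' @param planted_repeats list of [plant_spec()] objects.
#' @param base_composition probabilities for A, C, G, T.
#' @param L siRNA length the plants use.
#' @param flank flanking background sequence per contig (nt).
#' @param strands optional explicit strand vector; sampled otherwise.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_genes = 8L, gene_length_range = c(600L, 1500L),
                         gene_lengths = NULL,
                         exons_per_gene_range = c(1L, 4L),
                         intron_length_range = c(80L, 250L),
                         utr_lengths = c(60L, 90L),
                         planted_repeats = list(),
                         base_composition = rep(0.25, 4),
                         L = 21L, flank = 60L, strands = NULL) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8, length(base_composition) == 4L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 gene_lengths = if (is.null(gene_lengths)) NULL else
                   rep_len(as.integer(gene_lengths), n_genes),
                 exons_per_gene_range = exons_per_gene_range,
                 intron_length_range = intron_length_range,
                 utr_lengths = utr_lengths, planted_repeats = planted_repeats,
                 base_composition = base_composition, L = as.integer(L),
                 flank = as.integer(flank), strands = strands),
            class = "fixture_spec")
}

#' Specification of one planted repeat
#'
#' @param source_gene,target_gene 1-based gene indices into the fixture.
#' @param source_starts 0-based cDNA offsets of the source windows.
#' @param target_region `"exon"`, `"intron"` or `"utr"` — where in the
#'   target gene the copies land (each copy lies wholly inside one interval
#'   of that region).
#' @param mismatches_each Hamming distance of each copy from its source
#'   window (recycled to `length(source_starts)`).
#' @param orientation `"sense"` or `"revcomp"` placement of the copies.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(source_gene, source_starts, target_gene,
                       target_region = c("exon", "intron", "utr"),
                       mismatches_each = 0L,
                       orientation = c("sense", "revcomp")) {
  target_region <- match.arg(target_region)
  orientation <- match.arg(orientation)
  structure(list(source_gene = as.integer(source_gene),
                 source_starts = as.integer(source_starts),
                 target_gene = as.integer(target_gene),
                 target_region = target_region,
                 mismatches_each = rep_len(as.integer(mismatches_each),
                                           length(source_starts)),
                 orientation = orientation),
            class = "plant_spec")
}

#' Mutate a DNA string to an exact Hamming distance
#'
#' Substitutes `m` distinct positions with a different base, so the result
#' is at Hamming distance exactly `m` from the input. Deterministic given
#' `seed`; with `seed = NULL` the current RNG stream is used.
#'
#' @param s DNA string over \{A,C,G,T\}.
#' @param m number of substitutions, `0 <= m <= nchar(s)`.
#' @param seed optional integer seed.
#' @return the mutated string.
#' @export
mutate_with_hamming <- function(s, m, seed = NULL) {
  run <- function() {
    n <- nchar(s)
    stopifnot(m >= 0L, m <= n)
    if (m == 0L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    pos <- sample.int(n, m)
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## Internal per-gene structure in gene-local (strand-corrected) coordinates.
.fixture_gene_structure <- function(spec, i) {
  min_exon <- spec$L + max(spec$utr_lengths) + 10L
  Li <- if (!is.null(spec$gene_lengths)) spec$gene_lengths[i] else
    sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], 1L)
  n_ex <- sample(spec$exons_per_gene_range[1L]:spec$exons_per_gene_range[2L], 1L)
  while (n_ex > 1L && Li < n_ex * min_exon) n_ex <- n_ex - 1L
  if (Li < min_exon) Li <- min_exon
  extra <- Li - n_ex * min_exon
  add <- if (extra > 0L) {
    as.integer(stats::rmultinom(1L, extra, rep(1 / n_ex, n_ex)))
  } else rep(0L, n_ex)
  exon_len <- min_exon + add
  intron_len <- if (n_ex > 1L) {
    sample(spec$intron_length_range[1L]:spec$intron_length_range[2L],
           n_ex - 1L, replace = TRUE)
  } else integer(0)
  pieces <- integer(0)
  for (e in seq_len(n_ex)) {
    pieces <- c(pieces, exon_len[e])
    if (e < n_ex) pieces <- c(pieces, intron_len[e])
  }
  bounds <- cumsum(c(0L, pieces))
  is_exon <- rep(c(TRUE, FALSE), length.out = length(pieces))
  exons <- cbind(start = bounds[-length(bounds)][is_exon],
                 end = bounds[-1L][is_exon])
  introns <- if (any(!is_exon)) {
    cbind(start = bounds[-length(bounds)][!is_exon],
          end = bounds[-1L][!is_exon])
  } else cbind(start = integer(0), end = integer(0))
  local_len <- sum(pieces)
  u5 <- min(spec$utr_lengths[1L], exon_len[1L] - spec$L - 1L)
  u3 <- min(spec$utr_lengths[2L], exon_len[n_ex] - spec$L - 1L)
  utr5 <- if (u5 > 0L) cbind(start = exons[1L, 1L],
                             end = exons[1L, 1L] + u5) else
    cbind(start = integer(0), end = integer(0))
  utr3 <- if (u3 > 0L) cbind(start = exons[n_ex, 2L] - u3,
                             end = exons[n_ex, 2L]) else
    cbind(start = integer(0), end = integer(0))
  list(local_len = local_len, exons = exons, introns = introns,
       utr5 = utr5, utr3 = utr3, mature_len = sum(exon_len),
       seq = random_dna(local_len, spec$base_composition))
}

.mature_of <- function(g) {
  paste(substring(g$seq, g$exons[, 1L] + 1L, g$exons[, 2L]), collapse = "")
}

## Pick a placement interval of width L inside the requested region,
## avoiding already-used intervals. Returns the local start.
.place_plant <- function(g, region, L, used, label) {
  ivls <- switch(region, exon = g$exons, intron = g$introns,
                 utr = rbind(g$utr5, g$utr3))
  ivls <- ivls[ivls[, 2L] - ivls[, 1L] >= L, , drop = FALSE]
  if (nrow(ivls) == 0L) {
    stop(sprintf("infeasible plant %s: no %s interval of length >= %d in target",
                 label, region, L), call. = FALSE)
  }
  starts <- unlist(lapply(seq_len(nrow(ivls)), function(i) {
    ivls[i, 1L]:(ivls[i, 2L] - L)
  }), use.names = FALSE)
  ok <- vapply(starts, function(a) {
    !any(a < used[, 2L] & used[, 1L] < a + L)
  }, logical(1))
  if (!any(ok)) {
    stop(sprintf("infeasible plant %s: no %s placement without overlap",
                 label, region), call. = FALSE)
  }
  starts <- starts[ok]
  starts[sample.int(length(starts), 1L)]
}

#' Generate a synthetic fixture genome
#'
#' Writes `genome.fa`, `genes.gff3` and `truth.tsv` (the planted ground
#' truth) under `dir`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with file paths, the gene/contig naming, and the truth
#'   data.frame (`source_gene`, `source_start`, `target_gene`,
#'   `mismatches`, `region`, `orientation`, `target_local_start`).
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    genes <- lapply(seq_len(spec$n_genes), function(i) {
      .fixture_gene_structure(spec, i)
    })
    strands <- if (is.null(spec$strands)) {
      sample(c("+", "-"), spec$n_genes, replace = TRUE)
    } else rep_len(spec$strands, spec$n_genes)

    used <- lapply(seq_len(spec$n_genes), function(i) {
      cbind(start = integer(0), end = integer(0))
    })
    truth <- list()
    for (pi in seq_along(spec$planted_repeats)) {
      p <- spec$planted_repeats[[pi]]
      stopifnot(inherits(p, "plant_spec"),
                p$source_gene >= 1L, p$source_gene <= spec$n_genes,
                p$target_gene >= 1L, p$target_gene <= spec$n_genes)
      mature_src <- .mature_of(genes[[p$source_gene]])
      for (j in seq_along(p$source_starts)) {
        s <- p$source_starts[j]
        if (s < 0L || s + spec$L > nchar(mature_src)) {
          stop(sprintf("plant %d: source start %d outside cDNA of gene %d",
                       pi, s, p$source_gene), call. = FALSE)
        }
        frag <- substring(mature_src, s + 1L, s + spec$L)
        frag <- mutate_with_hamming(frag, p$mismatches_each[j])
        if (p$orientation == "revcomp") frag <- reverse_complement(frag)
        tg <- genes[[p$target_gene]]
        a <- .place_plant(tg, p$target_region, spec$L, used[[p$target_gene]],
                          sprintf("%d.%d", pi, j))
        substring(genes[[p$target_gene]]$seq, a + 1L, a + spec$L) <- frag
        used[[p$target_gene]] <- rbind(used[[p$target_gene]],
                                       c(a, a + spec$L))
        truth[[length(truth) + 1L]] <- data.frame(
          source_gene = sprintf("FG%03d", p$source_gene), source_start = s,
          target_gene = sprintf("FG%03d", p$target_gene),
          mismatches = p$mismatches_each[j], region = p$target_region,
          orientation = p$orientation, target_local_start = a,
          stringsAsFactors = FALSE
        )
      }
    }

    contigs <- character(spec$n_genes)
    gff <- c("##gff-version 3")
    for (i in seq_len(spec$n_genes)) {
      g <- genes[[i]]
      fl5 <- random_dna(spec$flank, spec$base_composition)
      fl3 <- random_dna(spec$flank, spec$base_composition)
      body <- if (strands[i] == "+") g$seq else reverse_complement(g$seq)
      contigs[i] <- paste0(fl5, body, fl3)
      gid <- sprintf("FG%03d", i)
      tid <- sprintf("FG%03d-RA", i)
      cid <- sprintf("contig%03d", i)
      to_genomic <- function(m) {
        if (nrow(m) == 0L) return(m)
        out <- if (strands[i] == "+") {
          cbind(start = spec$flank + m[, 1L], end = spec$flank + m[, 2L])
        } else {
          cbind(start = spec$flank + g$local_len - m[, 2L],
                end = spec$flank + g$local_len - m[, 1L])
        }
        out[order(out[, 1L]), , drop = FALSE]
      }
      line <- function(type, m, attrs) {
        sprintf("%s\tcotscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                cid, type, m[, 1L] + 1L, m[, 2L], strands[i], attrs)
      }
      span <- cbind(spec$flank, spec$flank + g$local_len)
      gff <- c(gff,
               line("gene", span, sprintf("ID=%s", gid)),
               line("mRNA", span, sprintf("ID=%s;Parent=%s", tid, gid)),
               line("exon", to_genomic(g$exons), sprintf("Parent=%s", tid)))
      if (nrow(g$utr5) > 0L) {
        gff <- c(gff, line("five_prime_UTR", to_genomic(g$utr5),
                           sprintf("Parent=%s", tid)))
      }
      if (nrow(g$utr3) > 0L) {
        gff <- c(gff, line("three_prime_UTR", to_genomic(g$utr3),
                           sprintf("Parent=%s", tid)))
      }
    }

    fasta_path <- file.path(dir, "genome.fa")
    gff_path <- file.path(dir, "genes.gff3")
    truth_path <- file.path(dir, "truth.tsv")
    dss <- Biostrings::DNAStringSet(contigs)
    names(dss) <- sprintf("contig%03d", seq_len(spec$n_genes))
    Biostrings::writeXStringSet(dss, fasta_path)
    writeLines(gff, gff_path)
    truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(source_gene = character(0), source_start = integer(0),
                 target_gene = character(0), mismatches = integer(0),
                 region = character(0), orientation = character(0),
                 target_local_start = integer(0), stringsAsFactors = FALSE)
    utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(spec = spec, dir = dir, fasta = fasta_path, gff = gff_path,
         truth_path = truth_path, truth = truth_df,
         gene_ids = sprintf("FG%03d", seq_len(spec$n_genes)),
         strands = strands)
  })
}
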