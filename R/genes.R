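#' Generate gene models and write their CDS into the genome
#'
#' Places non-overlapping protein-coding genes on both strands.  Each gene's
#' CDS (one or two exons) starts with ATG, contains no internal stop codon,
#' ends with a stop codon, and has length divisible by three; the coding
#' sequence is written into the returned copy of the genome so that
#' translation-based effect prediction is exact.
#'
#' @param genome a `DNAStringSet` genome (will be modified and returned).
#' @param n_genes number of genes to place.
#' @param cds_length_codons length-2 integer range of CDS lengths in codons
#'   (including start and stop).
#' @param two_exon_fraction fraction of genes receiving an intron.
#' @param seed integer seed, or `NULL`.
#' @return list with elements `genome` (modified `DNAStringSet`) and `genes`,
#'   a data.frame with one row per CDS interval: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `exon`, `translatable`.
#' @export
generate_gene_models <- function(genome, n_genes,
                                 cds_length_codons = c(50L, 150L),
                                 two_exon_fraction = 0.2, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  widths <- Biostrings::width(genome)
  need <- n_genes * (3 * mean(cds_length_codons) + 300)
  if (need > 0.9 * sum(widths))
    stop("genome too small to place ", n_genes, " genes (capacity error)")

  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)

  occupied <- lapply(widths, function(w) logical(w))
  names(occupied) <- names(genome)
  rows <- list()

  for (i in seq_len(n_genes)) {
    n_cod <- sample(seq(cds_length_codons[1], cds_length_codons[2]), 1)
    cds <- paste0("ATG",
                  paste(sample(sense, n_cod - 2L, replace = TRUE),
                        collapse = ""),
                  sample(stops, 1))
    strand <- sample(c("+", "-"), 1)
    two_exon <- stats::runif(1) < two_exon_fraction
    intron_len <- if (two_exon) sample(60:150, 1) else 0L
    cds_len <- nchar(cds)
    span <- cds_len + intron_len

    placed <- FALSE
    for (try in 1:200) {
      chrom <- sample(names(genome), 1, prob = widths)
      w <- widths[[match(chrom, names(genome))]]
      if (w < span + 200) next
      s <- sample.int(w - span - 100L, 1) + 50L
      if (any(occupied[[chrom]][s:(s + span + 19L)])) next
      occupied[[chrom]][max(1L, s - 20L):(s + span + 19L)] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("genome too small to place ", n_genes, " genes (capacity error)")

    # genomic plus-strand sequence of the CDS intervals, in genomic order,
    # must read as the CDS (plus strand) or its reverse complement (minus)
    genomic_cds <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    if (two_exon) {
      split_at <- sample(seq(3L, cds_len - 3L), 1)
      pieces <- c(substr(genomic_cds, 1L, split_at),
                  substr(genomic_cds, split_at + 1L, cds_len))
      starts <- c(s, s + split_at + intron_len)
    } else {
      pieces <- genomic_cds
      starts <- s
    }
    gid <- sprintf("gene%03d", i)
    for (k in seq_along(pieces)) {
      e <- starts[k] + nchar(pieces[k]) - 1L
      Biostrings::subseq(genome[[chrom]], starts[k], e) <-
        Biostrings::DNAString(pieces[k])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = starts[k], end = e, exon = k, translatable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genome = genome, genes = genes)
}

#' Spliced CDS sequence of one gene
#'
#' Concatenates the gene's CDS intervals in genomic order and reverse
#' complements for minus-strand genes, yielding the coding sequence 5'->3'.
#'
#' @param genes gene model data.frame (see [generate_gene_models()]).
#' @param genome a `DNAStringSet` genome.
#' @param gene_id gene identifier.
#' @return character scalar coding sequence.
#' @export
cds_sequence <- function(genes, genome, gene_id) {
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene_id: ", gene_id)
  g <- g[order(g$start), , drop = FALSE]
  s <- paste(mapply(function(a, b) genome_slice(genome, g$chrom[1], a, b),
                    g$start, g$end),
             collapse = "")
  if (g$strand[1] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Read gene models from GFF3
#'
#' Keeps CDS features of protein-coding genes, grouped per gene using the
#' first-listed transcript only.  Features typed `pseudogene` or
#' `transposable_element_gene` are skipped.  Genes whose total CDS length is
#' not divisible by three are flagged `translatable = FALSE` with a warning.
#'
#' @param path GFF3 file (optionally gzipped).
#' @return gene model data.frame (one row per CDS interval).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), exon = integer(),
                      translatable = logical(), stringsAsFactors = FALSE)
  if (length(gr) == 0) return(empty)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))

  skip_genes <- ids[type %in% c("pseudogene", "transposable_element_gene")]
  gene_of_tx <- parents[type == "mRNA"]
  names(gene_of_tx) <- ids[type == "mRNA"]

  cds <- which(type == "CDS")
  if (length(cds) == 0) return(empty)
  tx <- parents[cds]
  gene <- ifelse(tx %in% names(gene_of_tx), gene_of_tx[tx], tx)
  keep <- !(gene %in% skip_genes) & !is.na(gene)
  # first-listed transcript per gene only
  first_tx <- tapply(tx[keep], gene[keep], function(x) x[1])
  keep <- keep & tx %in% first_tx

  idx <- cds[keep]
  genes <- data.frame(
    gene_id = gene[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    start = GenomicRanges::start(gr)[idx],
    end = GenomicRanges::end(gr)[idx],
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id, genes$start), , drop = FALSE]
  genes$exon <- stats::ave(genes$start, genes$gene_id,
                           FUN = seq_along)
  tot <- tapply(genes$end - genes$start + 1L, genes$gene_id, sum)
  bad <- names(tot)[tot %% 3L != 0L]
  if (length(bad))
    warning("CDS length not divisible by 3; flagged non-translatable: ",
            paste(bad, collapse = ", "))
  genes$translatable <- !(genes$gene_id %in% bad)
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive) with ID/Parent
#' attributes, one transcript per gene.
#'
#' @param genes gene model data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    lo <- min(g$start); hi <- max(g$end)
    tx <- paste0(gid, ".1")
    writeLines(c(
      paste(g$chrom[1], "radmut", "gene", lo, hi, ".", g$strand[1], ".",
            paste0("ID=", gid), sep = "\t"),
      paste(g$chrom[1], "radmut", "mRNA", lo, hi, ".", g$strand[1], ".",
            paste0("ID=", tx, ";Parent=", gid), sep = "\t")), con)
    phase <- 0L
    rows <- if (g$strand[1] == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
    phases <- integer(nrow(g))
    for (k in rows) {
      phases[k] <- phase
      phase <- (3L - ((g$end[k] - g$start[k] + 1L - phase) %% 3L)) %% 3L
    }
    for (k in seq_len(nrow(g)))
      writeLines(paste(g$chrom[1], "radmut", "CDS", g$start[k], g$end[k],
                       ".", g$strand[1], phases[k],
                       paste0("ID=cds-", tx, ";Parent=", tx), sep = "\t"),
                 con)
  }
  invisible(path)
}
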