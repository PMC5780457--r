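#' Generate a random reference genome
#'
#' Draws chromosome sequences over A/C/G/T with a target GC content.  With
#' `homopolymer_enrichment > 0` the generator becomes a copying Markov chain:
#' at each position the previous base is repeated with a probability that
#' grows with the enrichment weight, which raises the density of mononucleotide
#' runs (>= 3 bp) above the i.i.d. expectation while leaving the marginal base
#' composition unchanged.
#'
#' @param total_length total genome size in bp (split across chromosomes),
#'   at least 10 kb.
#' @param n_chromosomes number of chromosomes.
#' @param gc_fraction target GC content in (0, 1).
#' @param homopolymer_enrichment non-negative weight; 0 gives i.i.d. bases.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @export
generate_reference <- function(total_length, n_chromosomes = 1L,
                               gc_fraction = 0.36,
                               homopolymer_enrichment = 0, seed = NULL) {
  if (!is.numeric(total_length) || total_length < 1e4)
    stop("total_length must be at least 10 kb")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly between 0 and 1")
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  if (homopolymer_enrichment < 0) stop("homopolymer_enrichment must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  lens <- rep(floor(total_length / n_chromosomes), n_chromosomes)
  lens[1] <- lens[1] + (total_length - sum(lens))
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  w <- homopolymer_enrichment / (homopolymer_enrichment + 12)

  seqs <- vapply(lens, function(n) {
    iid <- sample(bases, n, replace = TRUE, prob = p)
    if (w > 0) {
      keep <- c(TRUE, stats::runif(n - 1) >= w)
      idx <- cummax(ifelse(keep, seq_len(n), 0L))
      iid <- iid[idx]
    }
    paste(iid, collapse = "")
  }, character(1))

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chromosomes))
  genome
}

#' Coerce named character sequences to a genome object
#'
#' Convenience wrapper used throughout the package and its tests: a genome is
#' simply a named [Biostrings::DNAStringSet].
#'
#' @param x named character vector of sequences.
#' @return a `DNAStringSet`.
#' @export
as_genome <- function(x) {
  g <- Biostrings::DNAStringSet(toupper(x))
  if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == ""))
    stop("all sequences must be named")
  g
}

#' Total genome length in bp
#' @param genome a `DNAStringSet` genome.
#' @return integer total length.
#' @export
genome_length <- function(genome) sum(Biostrings::width(genome))

#' Extract a reference subsequence (1-based, inclusive)
#'
#' Coordinates outside the chromosome are clipped, so flank lookups near
#' chromosome ends return the available bases; `start > end` returns `""`.
#'
#' @param genome a `DNAStringSet` genome.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return character scalar.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- length(genome[[chrom]])
  start <- max(1L, start)
  end <- min(n, end)
  if (start > end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased and chromosome labels are the FASTA headers
#' truncated at the first whitespace.  Duplicate labels are a format error;
#' non-IUPAC characters are rejected by the underlying parser.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return a `DNAStringSet` genome.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate chromosome label in FASTA: ",
         names(g)[duplicated(names(g))][1])
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome to FASTA
#' @param genome a `DNAStringSet` genome.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

## run-length view of one chromosome: data.frame(start, length, base)
.seq_runs <- function(seq_string) {
  r <- rle(strsplit(seq_string, "", fixed = TRUE)[[1]])
  data.frame(start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
             length = r$lengths, base = r$values,
             stringsAsFactors = FALSE)
}

## count of mononucleotide runs of length >= min_run across the genome
.count_runs <- function(genome, min_run = 3L) {
  sum(vapply(as.character(genome), function(s) {
    sum(.seq_runs(s)$length >= min_run)
  }, numeric(1)))
}
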