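#' Write calls for one sample as VCF 4.2
#'
#' Minimal single-sample VCF with `GT:AD:DP` genotype fields; symbolic
#' `<DEL>` records carry `END` in INFO.  The genotype is a display heuristic
#' (`1/1` at AF >= 0.8, else `0/1`); the pipeline itself uses only AD/DP.
#'
#' @param calls calls data.frame rows for one sample.
#' @param genome genome used for contig headers.
#' @param path output file.
#' @param sample_id sample column label.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radmut",
               paste0("##contig=<ID=", names(genome), ",length=",
                      Biostrings::width(genome), ">"),
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of symbolic deletion\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_id, sep = "\t")), con)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    info <- ifelse(!is.na(calls$sv_end), paste0("END=", calls$sv_end), ".")
    gt <- ifelse(calls$af >= 0.8, "1/1", "0/1")
    ad <- paste(calls$depth - calls$mutant_reads, calls$mutant_reads,
                sep = ",")
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                     ".", "PASS", info, "GT:AD:DP",
                     paste(gt, ad, calls$depth, sep = ":"), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read per-sample variant calls from a VCF
#'
#' Parses a VCF 4.x (optionally gzipped) through `vcfR` and returns the
#' canonical calls data.frame.  Multi-allelic records are split into one call
#' per alternate allele; AF is computed from the AD field (mutant reads /
#' depth).  Records without usable depth get `depth = 0` and `af = NA` and
#' are excluded downstream with an explicit trace.
#'
#' @param path VCF file.
#' @param sample_id label for the calls; defaults to the VCF sample column.
#' @return calls data.frame (`sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `mutant_reads`, `depth`, `af`, `sv_end`).
#' @export
read_vcf_calls <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      mutant_reads = integer(), depth = integer(),
                      af = numeric(), sv_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0) return(empty)
  if (is.null(sample_id))
    sample_id <- colnames(v@gt)[2]
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ad <- as.character(vcfR::extract.gt(v, element = "AD")[, 1])
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  end <- suppressWarnings(as.integer(sub(".*END=([0-9]+).*", "\\1",
                                         ifelse(grepl("END=", fix$INFO),
                                                fix$INFO, NA))))
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    counts <- suppressWarnings(as.integer(
      strsplit(ifelse(is.na(ad[i]), "", ad[i]), ",", fixed = TRUE)[[1]]))
    depth <- if (!is.na(dp[i])) dp[i]
             else if (length(counts) && !anyNA(counts)) sum(counts)
             else 0L
    data.frame(sample_id = sample_id, chrom = fix$CHROM[i],
               pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts,
               mutant_reads = vapply(seq_along(alts), function(k) {
                 if (length(counts) >= k + 1 && !is.na(counts[k + 1]))
                   counts[k + 1] else 0L
               }, integer(1)),
               depth = depth, sv_end = end[i], stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$af <- ifelse(calls$depth > 0, calls$mutant_reads / calls$depth,
                     NA_real_)
  calls[, c("sample_id", "chrom", "pos", "ref", "alt", "mutant_reads",
            "depth", "af", "sv_end")]
}

#' Read a cohort of per-sample VCFs
#' @param paths VCF files, one per sample.
#' @param sample_ids labels; default taken from file names.
#' @return combined calls data.frame.
#' @export
read_vcf_cohort <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.vcf(\\.gz)?$", "", basename(paths))
  do.call(rbind, mapply(read_vcf_calls, paths, sample_ids,
                        SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

## normalize one anchored (ref, alt, pos); `sl(lo, hi)` slices the
## chromosome sequence (1-based inclusive, clipped)
.normalize_one <- function(pos, ref, alt, sl) {
  if (startsWith(alt, "<")) return(list(pos = pos, ref = ref, alt = alt))
  # trim shared suffix, then shared prefix (keep >= 1 base each)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(list(pos = pos, ref = ref, alt = alt))
  if (nr > na && na == 1 && substr(ref, 1, 1) == alt) {
    # pure deletion: left-shift while the base before the deleted segment
    # equals its last base (deleted segment always re-read from reference)
    len <- nr - 1L
    d <- pos + 1L                       # first deleted base
    while (d > 1L && sl(d - 1L, d - 1L) == sl(d + len - 1L, d + len - 1L))
      d <- d - 1L
    anchor <- sl(d - 1L, d - 1L)
    return(list(pos = d - 1L,
                ref = paste0(anchor, sl(d, d + len - 1L)),
                alt = anchor))
  }
  if (na > nr && nr == 1 && substr(alt, 1, 1) == ref) {
    # pure insertion: rotate the inserted segment left while it matches the
    # anchor base
    seg <- substr(alt, 2, na)
    p <- pos
    while (p > 1L && sl(p, p) == substr(seg, nchar(seg), nchar(seg))) {
      seg <- paste0(substr(seg, nchar(seg), nchar(seg)),
                    substr(seg, 1, nchar(seg) - 1))
      p <- p - 1L
    }
    anchor <- sl(p, p)
    return(list(pos = p, ref = anchor, alt = paste0(anchor, seg)))
  }
  # mixed deletion+insertion: leave at trimmed representation
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant representation
#'
#' Trims shared prefix/suffix bases (keeping one anchor base for indels) and
#' left-aligns indels by iterated shifting while the flanking base permits.
#' Substitutions are reduced to their minimal changed block.  The operation
#' is idempotent and never changes a variant's net length; downstream context
#' calls are therefore invariant to the input VCF's alignment dialect.
#'
#' @param calls calls data.frame.
#' @param genome reference genome (`DNAStringSet`).
#' @return calls data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(calls, genome) {
  if (nrow(calls) == 0) return(calls)
  for (cc in unique(calls$chrom)) {
    if (!cc %in% names(genome)) stop("unknown chromosome: ", cc)
    s <- as.character(genome[[cc]])
    n <- nchar(s)
    sl <- function(lo, hi) substr(s, max(1L, lo), min(n, hi))
    idx <- which(calls$chrom == cc)
    # substitutions need no reference lookups; skip pure SNVs quickly
    for (i in idx) {
      ref <- calls$ref[i]; alt <- calls$alt[i]
      if (nchar(ref) == 1L && nchar(alt) == 1L) next
      nn <- .normalize_one(calls$pos[i], ref, alt, sl)
      calls$pos[i] <- nn$pos
      calls$ref[i] <- nn$ref
      calls$alt[i] <- nn$alt
    }
  }
  calls
}
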