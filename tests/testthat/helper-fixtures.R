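# Small in-code fixtures shared across the suite.

# calls data.frame constructor with sensible defaults
make_calls <- function(sample_id, chrom, pos, ref, alt,
                       mutant_reads = 15L, depth = 30L,
                       zygosity = NULL, sv_end = NA_integer_) {
  d <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                  ref = ref, alt = alt, mutant_reads = mutant_reads,
                  depth = depth, sv_end = sv_end, stringsAsFactors = FALSE)
  d$af <- ifelse(d$depth > 0, d$mutant_reads / d$depth, NA_real_)
  if (!is.null(zygosity)) d$zygosity <- zygosity
  d
}

# one-row events data.frame for direct detector calls
make_event <- function(category, chrom, start, end, deleted_seq = "",
                       inserted_seq = "", net_length = NULL,
                       zygosity = "HET", sample_id = "s1",
                       sv_end = NA_integer_) {
  if (is.null(net_length))
    net_length <- nchar(inserted_seq) - nchar(deleted_seq)
  data.frame(event_id = paste0(sample_id, ":", chrom, ":", start),
             sample_id = sample_id, chrom = chrom, start = start,
             end = end, category = category, net_length = net_length,
             deleted_seq = deleted_seq, inserted_seq = inserted_seq,
             ref_allele = NA_character_, alt_allele = NA_character_,
             zygosity = zygosity, mixed_zygosity = FALSE,
             n_constituents = 1L, n_separators = 0L, sv_end = sv_end,
             af_mean = 0.5, stringsAsFactors = FALSE)
}

# events for samples with given counts (all isolated substitutions)
make_sample_events <- function(counts, category = "SBS") {
  rows <- lapply(names(counts), function(sid) {
    n <- counts[[sid]]
    if (n == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(k)
      make_event(category, "chr1", k * 100L, k * 100L, sample_id = sid)))
  })
  do.call(rbind, rows)
}

# random genome as plain character string
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force microhomology oracle: largest k (<= cap) with an exact
# suffix(U)/prefix-of-D match or prefix(D)/prefix(W) match
mh_oracle <- function(U, D, W, max_len = 10L) {
  cap <- min(nchar(D), max_len)
  best <- 0L
  for (k in seq_len(cap)) {
    if (nchar(U) >= k &&
        substr(U, nchar(U) - k + 1L, nchar(U)) == substr(D, nchar(D) - k + 1L,
                                                         nchar(D)))
      best <- max(best, k)
    if (nchar(W) >= k && substr(D, 1L, k) == substr(W, 1L, k))
      best <- max(best, k)
  }
  best
}

# maximal-run counter by explicit linear scan (oracle for run statistics)
scan_runs_ge <- function(s, min_run = 3L) {
  v <- strsplit(s, "")[[1]]
  n <- 0L; i <- 1L
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
    if (j - i + 1L >= min_run) n <- n + 1L
    i <- j + 1L
  }
  n
}
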