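## Sequence-context signatures of indel events: homopolymer runs,
## polynucleotide (tandem) repeats, and junction microhomology.

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d)) d[1] - 1L else n
}

.common_suffix_len <- function(a, b) {
  .common_prefix_len(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
                     paste(rev(strsplit(b, "")[[1]]), collapse = ""))
}

.is_uniform <- function(x) {
  if (is.character(x) && length(x) == 1) x <- strsplit(x, "")[[1]]
  length(unique(x)) == 1
}

## tandem repeat intervals in a window: >= min_copies exact copies of a unit
## of length in unit_range; period-1 (homopolymer) units are excluded
.tandem_intervals <- function(window, unit_range = 2:6, min_copies = 2L) {
  v <- strsplit(window, "")[[1]]
  L <- length(v)
  out <- list()
  for (u in unit_range) {
    if (L < min_copies * u) next
    i <- 1L
    while (i <= L - 2L * u + 1L) {
      unit <- v[i:(i + u - 1L)]
      if (.is_uniform(unit)) { i <- i + 1L; next }
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= L &&
             identical(v[(i + copies * u):(i + (copies + 1L) * u - 1L)],
                       unit))
        copies <- copies + 1L
      if (copies >= min_copies) {
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = i + copies * u - 1L,
          unit = paste(unit, collapse = ""), stringsAsFactors = FALSE)
        i <- i + copies * u
      } else i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), end = integer(), unit = character(),
                  stringsAsFactors = FALSE)
}

.has_tandem_overlap <- function(window, fp_start, fp_end,
                                unit_range = 2:6, min_copies = 2L) {
  tr <- .tandem_intervals(window, unit_range, min_copies)
  any(tr$start <= fp_end & tr$end >= fp_start)
}

## does a tandem run span the boundary between window positions b and b+1?
.tandem_at_boundary <- function(window, b, unit_range = 2:6,
                                min_copies = 2L) {
  tr <- .tandem_intervals(window, unit_range, min_copies)
  hit <- tr$start <= b & tr$end >= b + 1L
  if (any(hit)) tr$unit[which(hit)[1]] else NA_character_
}

## tandem run spanning a junction at genomic boundary jpos/jpos+1; a
## spanning run of unit length <= max(unit_range) always contains a
## spanning two-copy pair within +/- 2*max(unit_range) of the boundary,
## so a local window suffices whatever the indel size
.junction_repeat <- function(genome, chrom, jpos, unit_range = 2:6,
                             min_copies = 2L) {
  r <- max(unit_range) * 2L
  lo <- max(1L, jpos - r + 1L)
  win <- genome_slice(genome, chrom, lo, jpos + r)
  .tandem_at_boundary(win, jpos - lo + 1L, unit_range, min_copies)
}

.assert_indel <- function(event,
                          cats = c("DEL1", "DEL_GE2", "INS1", "INS_GE2")) {
  if (!event$category %in% cats)
    stop("context detection is defined for categories ",
         paste(cats, collapse = ", "), "; got ", event$category)
}

#' Detect a homopolymer context at an indel
#'
#' An indel sits in a homopolymer when its changed segment is a run of one
#' base and the union of that segment with its flanking identical reference
#' bases reaches `min_run`.  For insertions the run is the post-insertion
#' run containing the insertion point.  Events are assumed left-aligned
#' (see [normalize_variants()]); the flag is alignment-invariant.
#'
#' @param genome reference genome.
#' @param event one-row events data.frame (indel category).
#' @param min_run minimum run length (default 3).
#' @return list with `flag`, `base`, `run`.
#' @export
detect_homopolymer <- function(genome, event, min_run = 3L) {
  .assert_indel(event)
  seg <- if (nzchar(event$deleted_seq)) event$deleted_seq
         else event$inserted_seq
  if (!.is_uniform(seg))
    return(list(flag = FALSE, base = NA_character_, run = 0L))
  b <- substr(seg, 1, 1)
  count_dir <- function(from, step) {
    k <- 0L
    p <- from
    while (genome_slice(genome, event$chrom, p, p) == b && p >= 1) {
      k <- k + 1L
      p <- p + step
    }
    k
  }
  if (nzchar(event$deleted_seq)) {
    run <- nchar(seg) + count_dir(event$start - 1L, -1L) +
      count_dir(event$end + 1L, 1L)
  } else {
    run <- nchar(seg) + count_dir(event$start, -1L) +
      count_dir(event$start + 1L, 1L)
  }
  list(flag = run >= min_run, base = b, run = run)
}

#' Detect a polynucleotide (tandem) repeat context at an indel
#'
#' For deletions: true when a tandem run of at least `min_copies` exact
#' copies of a 2-6 bp unit spans a deletion breakpoint (the junction between
#' the last retained and first deleted base, or between the last deleted and
#' first retained base) -- the misalignment/rejoining signature lives at the
#' breakpoints, so an incidental repeat buried deep inside a large deleted
#' segment does not count.  For insertions the inserted sequence is spliced
#' into the window first and the run must overlap the insertion (so a tandem
#' duplication is seen as a repeat).  Period-1 units are excluded:
#' homopolymers are reported by [detect_homopolymer()] instead.
#'
#' @param genome reference genome.
#' @param event one-row events data.frame (indel category).
#' @param unit_range repeat unit lengths to consider.
#' @param min_copies minimum number of exact tandem copies.
#' @return list with `flag`, `unit`.
#' @export
detect_polynucleotide_repeat <- function(genome, event, unit_range = 2:6,
                                         min_copies = 2L) {
  .assert_indel(event)
  flank <- 12L
  if (nzchar(event$deleted_seq)) {
    unit <- .junction_repeat(genome, event$chrom, event$start - 1L,
                             unit_range, min_copies)
    if (is.na(unit))
      unit <- .junction_repeat(genome, event$chrom, event$end,
                               unit_range, min_copies)
    list(flag = !is.na(unit), unit = unit)
  } else {
    lo <- max(1L, event$start - flank)
    left <- genome_slice(genome, event$chrom, lo, event$start)
    right <- genome_slice(genome, event$chrom, event$start + 1L,
                          event$start + flank)
    win <- paste0(left, event$inserted_seq, right)
    fp <- c(nchar(left) + 1L, nchar(left) + nchar(event$inserted_seq))
    tr <- .tandem_intervals(win, unit_range, min_copies)
    hit <- tr$start <= fp[2] + 1L & tr$end >= fp[1] - 1L
    if (any(hit)) list(flag = TRUE, unit = tr$unit[which(hit)[1]])
    else list(flag = FALSE, unit = NA_character_)
  }
}

#' Detect junction microhomology at a multi-base indel
#'
#' For a deletion of segment D with upstream flank U and downstream flank W,
#' the microhomology length is the larger of the longest common suffix of
#' (U, D) and the longest common prefix of (D, W), capped at `max_len` and
#' at the segment length; for insertions the inserted sequence takes the
#' role of D.  At the default `min_len = 2`, random sequence produces few
#' spurious flags; at `min_len = 1` roughly 1 - (3/4)^2 of junctions match
#' by chance, which is why 1 is not the default.
#'
#' @param genome reference genome.
#' @param event one-row events data.frame, category DEL_GE2 or INS_GE2.
#' @param min_len minimum homology length to flag (default 2).
#' @param max_len maximum homology length considered (default 10).
#' @return list with `flag`, `len`, `seq`.
#' @export
detect_microhomology <- function(genome, event, min_len = 2L,
                                 max_len = 10L) {
  .assert_indel(event, cats = c("DEL_GE2", "INS_GE2"))
  if (nzchar(event$deleted_seq)) {
    D <- event$deleted_seq
    U <- genome_slice(genome, event$chrom, event$start - max_len,
                      event$start - 1L)
    W <- genome_slice(genome, event$chrom, event$end + 1L,
                      event$end + max_len)
  } else {
    D <- event$inserted_seq
    U <- genome_slice(genome, event$chrom, event$start - max_len + 1L,
                      event$start)
    W <- genome_slice(genome, event$chrom, event$start + 1L,
                      event$start + max_len)
  }
  ls <- min(.common_suffix_len(U, D), max_len, nchar(D))
  lp <- min(.common_prefix_len(D, W), max_len, nchar(D))
  len <- max(ls, lp)
  seq <- if (len == 0) "" else if (lp >= ls) substr(D, 1, lp)
         else substr(D, nchar(D) - ls + 1L, nchar(D))
  list(flag = len >= min_len, len = len, seq = seq)
}

#' A/T versus G/C site class of a single-base indel
#'
#' @param event one-row events data.frame.
#' @return `"AT"`, `"GC"`, or `NA` for indels longer than one base.
#' @export
classify_site_base <- function(event) {
  if (!event$category %in% c("DEL1", "INS1")) return(NA_character_)
  b <- if (nzchar(event$deleted_seq)) event$deleted_seq
       else event$inserted_seq
  if (b %in% c("A", "T")) "AT" else if (b %in% c("G", "C")) "GC"
  else NA_character_
}

#' Annotate indel events with sequence contexts
#'
#' Runs homopolymer, polynucleotide-repeat and junction-microhomology
#' detection on every single-call indel event (COMPLEX and SV events carry
#' no context annotation).  The `primary_context` column applies the
#' priority homopolymer > repeat > microhomology for mutually exclusive
#' summaries; the raw flags are retained side by side and are not exclusive.
#'
#' @param events events data.frame from [merge_events()].
#' @param genome reference genome.
#' @param min_run,unit_range,min_copies,mh_min_len,mh_max_len detector
#'   parameters (see the individual detectors).
#' @return annotation data.frame keyed by `event_id`.
#' @export
annotate_events <- function(events, genome, min_run = 3L, unit_range = 2:6,
                            min_copies = 2L, mh_min_len = 2L,
                            mh_max_len = 10L) {
  idx <- which(events$category %in% c("DEL1", "DEL_GE2", "INS1", "INS_GE2"))
  rows <- lapply(idx, function(i) {
    ev <- events[i, ]
    hp <- detect_homopolymer(genome, ev, min_run)
    tr <- detect_polynucleotide_repeat(genome, ev, unit_range, min_copies)
    mh <- if (ev$category %in% c("DEL_GE2", "INS_GE2"))
      detect_microhomology(genome, ev, mh_min_len, mh_max_len)
    else list(flag = NA, len = NA_integer_, seq = NA_character_)
    primary <- if (isTRUE(hp$flag)) "homopolymer"
               else if (isTRUE(tr$flag)) "repeat"
               else if (isTRUE(mh$flag)) "microhomology" else "none"
    data.frame(event_id = ev$event_id, category = ev$category,
               homopolymer = hp$flag, homopolymer_base = hp$base,
               homopolymer_run = hp$run,
               tandem_repeat = tr$flag, repeat_unit = tr$unit,
               microhomology = mh$flag, microhomology_len = mh$len,
               microhomology_seq = mh$seq,
               site_base_class = classify_site_base(ev),
               primary_context = primary, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(event_id = character(), category = character(),
                  homopolymer = logical(), homopolymer_base = character(),
                  homopolymer_run = integer(), tandem_repeat = logical(),
                  repeat_unit = character(), microhomology = logical(),
                  microhomology_len = integer(),
                  microhomology_seq = character(),
                  site_base_class = character(),
                  primary_context = character(), stringsAsFactors = FALSE)
}

#' Summarize context associations per group and category
#'
#' Emits, per group and indel category, the number of events, the count and
#' percentage associated with a homopolymeric sequence, and the count and
#' percentage associated with a polynucleotide repeat or junction
#' microhomology (columns are not exclusive: an event flagged for both
#' counts once in each).  Multi-base deletions additionally get a breakdown
#' by size bin (`2-9`, `10-49`, `>=50`).  Percentages are rounded to
#' integers.
#'
#' @param events events data.frame.
#' @param annotations annotation data.frame from [annotate_events()].
#' @param manifest optional data.frame (`sample_id`, `group`); omit to pool
#'   all samples as one `combined` group.
#' @return summary data.frame with one row per group x category (x size
#'   bin for DEL_GE2; the whole-category row has `bin = "all"`).
#' @export
summarize_context <- function(events, annotations, manifest = NULL) {
  x <- merge(events, annotations, by = "event_id",
             suffixes = c("", ".ann"))
  x$group <- if (is.null(manifest)) "combined"
             else manifest$group[match(x$sample_id, manifest$sample_id)]
  x$rep_or_mh <- (x$tandem_repeat %in% TRUE) | (x$microhomology %in% TRUE)
  pct <- function(n, d) ifelse(d > 0, round(100 * n / d), NA)
  rows <- list()
  for (g in unique(x$group)) {
    for (cat in c("DEL1", "DEL_GE2", "INS1", "INS_GE2")) {
      sub <- x[x$group == g & x$category == cat, , drop = FALSE]
      if (nrow(sub) == 0) next
      add <- function(bin, d) {
        n <- nrow(d)
        single <- cat %in% c("DEL1", "INS1")
        n_at <- if (single) sum(d$site_base_class %in% "AT") else NA_integer_
        data.frame(group = g, category = cat, bin = bin, n = n,
                   n_homopolymer = sum(d$homopolymer %in% TRUE),
                   pct_homopolymer = pct(sum(d$homopolymer %in% TRUE), n),
                   n_repeat_or_mh = sum(d$rep_or_mh),
                   pct_repeat_or_mh = pct(sum(d$rep_or_mh), n),
                   n_at_site = n_at,
                   pct_at_site = if (single) pct(n_at, n) else NA_real_,
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- add("all", sub)
      if (cat == "DEL_GE2") {
        bins <- deletion_size_bin(sub$net_length)
        for (b in c("2-9", "10-49", ">=50")) {
          d <- sub[bins == b, , drop = FALSE]
          if (nrow(d)) rows[[length(rows) + 1L]] <- add(b, d)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
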