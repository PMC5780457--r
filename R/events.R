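#' Net length of a sequence alteration
#'
#' Signed alt-minus-ref length of the changed segments.  A deletion
#' accompanied by an insertion of other sequence is summarized by its net
#' change, e.g. a 10-base deletion with a 3-base insertion has net length -7
#' and counts as a 7-base deletion.
#'
#' @param ref_segment,alt_segment changed segments (anchors trimmed); either
#'   may be `""`.
#' @return integer net length (alt - ref).
#' @export
net_length <- function(ref_segment, alt_segment) {
  nchar(alt_segment) - nchar(ref_segment)
}

#' Category of a single normalized call
#'
#' Maps one ref/alt pair (anchored VCF or bare-segment representation) to
#' one of the seven mutation categories.  Equal-length single-base changes
#' are SBS; equal-length multi-base blocks with two or more changed bases
#' are consecutive substitutions and hence COMPLEX; indels map by net length
#' (`-1` DEL1, `<= -2` DEL_GE2, `+1` INS1, `>= +2` INS_GE2); symbolic
#' alleles are SV.
#'
#' @param ref,alt allele strings.
#' @return category string.
#' @export
variant_category <- function(ref, alt) {
  if (startsWith(alt, "<")) return("SV")
  if (ref == alt) stop("zero-length no-op edit cannot be classified")
  if (nchar(ref) == nchar(alt)) {
    rr <- strsplit(ref, "")[[1]]
    aa <- strsplit(alt, "")[[1]]
    n_changed <- sum(rr != aa)
    if (n_changed == 0) stop("zero-length no-op edit cannot be classified")
    return(if (nchar(ref) == 1 || n_changed == 1) "SBS" else "COMPLEX")
  }
  # anchored indels share a leading anchor base; compare past shared prefix
  p <- .common_prefix_len(ref, alt)
  net <- nchar(alt) - nchar(ref)
  if (net <= -1 && p >= nchar(alt)) {            # pure deletion
    return(if (net == -1) "DEL1" else "DEL_GE2")
  }
  if (net >= 1 && p >= nchar(ref)) {             # pure insertion
    return(if (net == 1) "INS1" else "INS_GE2")
  }
  # mixed deletion+insertion: classify by net change
  if (net <= -1) return(if (net == -1) "DEL1" else "DEL_GE2")
  if (net >= 1) return(if (net == 1) "INS1" else "INS_GE2")
  "COMPLEX"
}

## decompose normalized anchored calls into edits with reference footprints
## footprint: substitution [pos, pos+n-1]; deletion = deleted bases;
## insertion = the anchor base (a point between anchor and anchor+1)
.call_edits <- function(calls) {
  n <- nrow(calls)
  ed <- data.frame(type = character(n), fp_start = integer(n),
                   fp_end = integer(n), deleted = character(n),
                   inserted = character(n), net = integer(n),
                   indel_size = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ref <- calls$ref[i]; alt <- calls$alt[i]; pos <- calls$pos[i]
    if (startsWith(alt, "<")) {
      ed$type[i] <- "sv"
      ed$fp_start[i] <- pos
      ed$fp_end[i] <- if (!is.na(calls$sv_end[i])) calls$sv_end[i] else pos
      ed$net[i] <- NA_integer_
      ed$indel_size[i] <- NA_integer_
      next
    }
    if (nchar(ref) == nchar(alt)) {
      ed$type[i] <- "sub"
      ed$fp_start[i] <- pos
      ed$fp_end[i] <- pos + nchar(ref) - 1L
      ed$net[i] <- 0L
      ed$indel_size[i] <- nchar(ref)
      next
    }
    p <- .common_prefix_len(ref, alt)
    deleted <- substr(ref, p + 1L, nchar(ref))
    inserted <- substr(alt, p + 1L, nchar(alt))
    ed$type[i] <- "indel"
    ed$deleted[i] <- deleted
    ed$inserted[i] <- inserted
    ed$net[i] <- nchar(inserted) - nchar(deleted)
    ed$indel_size[i] <- max(nchar(deleted), nchar(inserted))
    if (nchar(deleted) > 0) {
      ed$fp_start[i] <- pos + p
      ed$fp_end[i] <- pos + nchar(ref) - 1L
    } else {
      ed$fp_start[i] <- pos + p - 1L
      ed$fp_end[i] <- pos + p - 1L
    }
  }
  ed
}

#' Merge filtered calls into mutation events
#'
#' Calls on one chromosome of one sample whose reference footprints are
#' separated by at most `merge_gap_max` unmutated bases (gap counted
#' strictly between footprints) are merged into a single COMPLEX event; the
#' merge is restricted to constituents shorter than 50 bp, so a large
#' deletion never joins a complex event.  Structural variants pass through
#' unmerged.  Internal runs of two or more reference-matching bases between
#' constituents are recorded as unmutated separators (`n_separators`).
#' Constituents with conflicting zygosity yield a `mixed_zygosity` event
#' reported as HET, the weaker claim.
#'
#' @param calls retained calls with `zygosity` (see [filter_calls()]),
#'   normalized against the reference.
#' @param policy a `radmut_policy` (uses `merge_gap_max`).
#' @return events data.frame: `event_id`, `sample_id`, `chrom`, `start`,
#'   `end`, `category`, `net_length`, `deleted_seq`, `inserted_seq`,
#'   `ref_allele`, `alt_allele` (single-base substitutions only),
#'   `zygosity`, `mixed_zygosity`, `n_constituents`, `n_separators`,
#'   `sv_end`, `af_mean`.
#' @export
merge_events <- function(calls, policy = filter_policy()) {
  empty <- data.frame(event_id = character(), sample_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), category = character(),
                      net_length = integer(), deleted_seq = character(),
                      inserted_seq = character(), ref_allele = character(),
                      alt_allele = character(), zygosity = character(),
                      mixed_zygosity = logical(), n_constituents = integer(),
                      n_separators = integer(), sv_end = integer(),
                      af_mean = numeric(), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  gap_max <- policy$merge_gap_max
  out <- list()
  for (sid in unique(calls$sample_id)) {
    sc <- calls[calls$sample_id == sid, , drop = FALSE]
    for (cc in unique(sc$chrom)) {
      x <- sc[sc$chrom == cc, , drop = FALSE]
      ed <- .call_edits(x)
      o <- order(ed$fp_start, ed$fp_end)
      x <- x[o, , drop = FALSE]
      ed <- ed[o, , drop = FALSE]
      mergeable <- ed$type != "sv" & ed$indel_size < 50L
      n <- nrow(x)
      cluster <- integer(n)
      cl <- 1L
      cluster[1] <- cl
      for (i in seq_len(n - 1L)) {
        gap <- ed$fp_start[i + 1L] - max(ed$fp_end[seq_len(i)][
          cluster[seq_len(i)] == cl]) - 1L
        if (mergeable[i] && mergeable[i + 1L] && gap <= gap_max) {
          cluster[i + 1L] <- cl
        } else {
          cl <- cl + 1L
          cluster[i + 1L] <- cl
        }
      }
      for (k in unique(cluster)) {
        idx <- which(cluster == k)
        xi <- x[idx, , drop = FALSE]
        ei <- ed[idx, , drop = FALSE]
        n_con <- length(idx)
        mixed <- length(unique(xi$zygosity)) > 1
        zyg <- if (mixed) "HET" else xi$zygosity[1]
        if (n_con == 1L) {
          category <- variant_category(xi$ref[1], xi$alt[1])
          net <- ei$net[1]
        } else {
          category <- "COMPLEX"
          net <- sum(ei$net)
        }
        gaps <- if (n_con > 1L)
          ei$fp_start[-1L] - ei$fp_end[-n_con] - 1L else integer(0)
        is_sbs <- category == "SBS"
        out[[length(out) + 1L]] <- list(
          event_id = paste0(sid, ":", cc, ":", ei$fp_start[1]),
          sample_id = sid, chrom = cc,
          start = as.integer(min(ei$fp_start)),
          end = as.integer(max(ei$fp_end)),
          category = category,
          net_length = as.integer(net),
          deleted_seq = paste(ei$deleted[nzchar(ei$deleted)], collapse = ""),
          inserted_seq = paste(ei$inserted[nzchar(ei$inserted)],
                               collapse = ""),
          ref_allele = if (is_sbs) xi$ref[1] else NA_character_,
          alt_allele = if (is_sbs) xi$alt[1] else NA_character_,
          zygosity = zyg, mixed_zygosity = mixed,
          n_constituents = n_con,
          n_separators = sum(gaps >= 2L),
          sv_end = as.integer(xi$sv_end[1]),
          af_mean = mean(xi$af))
      }
    }
  }
  ev <- data.frame(
    event_id = vapply(out, `[[`, character(1), "event_id"),
    sample_id = vapply(out, `[[`, character(1), "sample_id"),
    chrom = vapply(out, `[[`, character(1), "chrom"),
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    category = vapply(out, `[[`, character(1), "category"),
    net_length = vapply(out, `[[`, integer(1), "net_length"),
    deleted_seq = vapply(out, `[[`, character(1), "deleted_seq"),
    inserted_seq = vapply(out, `[[`, character(1), "inserted_seq"),
    ref_allele = vapply(out, `[[`, character(1), "ref_allele"),
    alt_allele = vapply(out, `[[`, character(1), "alt_allele"),
    zygosity = vapply(out, `[[`, character(1), "zygosity"),
    mixed_zygosity = vapply(out, `[[`, logical(1), "mixed_zygosity"),
    n_constituents = vapply(out, `[[`, integer(1), "n_constituents"),
    n_separators = vapply(out, `[[`, integer(1), "n_separators"),
    sv_end = vapply(out, `[[`, integer(1), "sv_end"),
    af_mean = vapply(out, `[[`, numeric(1), "af_mean"),
    stringsAsFactors = FALSE)
  ev <- ev[order(ev$sample_id, ev$chrom, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Deletion size bin
#'
#' Maps deletion net lengths to the size bins `1`, `2-9`, `10-49`, `>=50`.
#'
#' @param net_length negative net lengths of deletion events.
#' @return factor of bins.
#' @export
deletion_size_bin <- function(net_length) {
  if (any(is.na(net_length)) || any(net_length >= 0))
    stop("deletion_size_bin is defined for deletion events (net length < 0)")
  cut(abs(net_length), breaks = c(0, 1, 9, 49, Inf),
      labels = c("1", "2-9", "10-49", ">=50"))
}
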