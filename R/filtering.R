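#' Filtering and zygosity policy
#'
#' Thresholds for the cohort filtering rules: candidate calls need at least
#' `min_mutant_reads` mutant reads; calls at AF <= `af_exclude_max` are
#' excluded as unreliable; a call is heterozygous when its AF lies strictly
#' inside (`het_min_af`, `het_max_af`) and homozygous when AF >=
#' `hom_min_af`, in both cases provided every other sample's AF at the site
#' is below `cross_sample_max_af`; a site+allele seen (above that AF) in
#' more than `background_max_samples` samples is a background artifact and
#' removed everywhere.
#'
#' @param min_mutant_reads minimum mutant read support (default 3).
#' @param af_exclude_max exclusion ceiling, inclusive (default 0.25).
#' @param het_min_af,het_max_af heterozygous AF band, both exclusive
#'   (defaults 0.25 and 0.80).
#' @param hom_min_af homozygous AF floor, inclusive (default 0.80).
#' @param cross_sample_max_af other-sample AF ceiling, exclusive
#'   (default 0.05).
#' @param background_max_samples maximum number of samples a genuine
#'   mutation may appear in (default 2).
#' @param min_consecutive_sbs_complex number of immediately consecutive
#'   substitutions that form a complex event (default 2).
#' @param merge_gap_max maximum number of unmutated reference bases between
#'   constituents of one complex event (default 9, i.e. "gap < 10").
#' @return a `radmut_policy` list.
#' @export
filter_policy <- function(min_mutant_reads = 3L,
                          af_exclude_max = 0.25,
                          het_min_af = 0.25, het_max_af = 0.80,
                          hom_min_af = 0.80,
                          cross_sample_max_af = 0.05,
                          background_max_samples = 2L,
                          min_consecutive_sbs_complex = 2L,
                          merge_gap_max = 9L) {
  if (!(0 <= af_exclude_max && af_exclude_max <= het_min_af &&
        het_min_af < het_max_af && het_max_af <= hom_min_af &&
        hom_min_af <= 1))
    stop("policy thresholds must satisfy 0 <= af_exclude_max <= het_min_af",
         " < het_max_af <= hom_min_af <= 1")
  structure(list(min_mutant_reads = min_mutant_reads,
                 af_exclude_max = af_exclude_max,
                 het_min_af = het_min_af, het_max_af = het_max_af,
                 hom_min_af = hom_min_af,
                 cross_sample_max_af = cross_sample_max_af,
                 background_max_samples = background_max_samples,
                 min_consecutive_sbs_complex = min_consecutive_sbs_complex,
                 merge_gap_max = merge_gap_max),
            class = "radmut_policy")
}

#' Read a filter policy from YAML or JSON
#' @param path config file with fields matching [filter_policy()].
#' @return a `radmut_policy`.
#' @export
read_policy <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(filter_policy, cfg)
}

#' Read-support filter
#'
#' Retains exactly the calls with at least `min_mutant_reads` mutant reads.
#'
#' @param calls calls data.frame.
#' @param policy a `radmut_policy`.
#' @return filtered calls data.frame.
#' @export
apply_support_filter <- function(calls, policy = filter_policy()) {
  calls[calls$mutant_reads >= policy$min_mutant_reads, , drop = FALSE]
}

.site_key <- function(calls) paste(calls$chrom, calls$pos, calls$ref,
                                   calls$alt, sep = ":")

#' Remove cross-sample background artifacts
#'
#' A site+allele present with AF above `cross_sample_max_af` in more than
#' `background_max_samples` samples is removed from every sample.  Site
#' matching uses (chromosome, normalized position, ref, alt).
#'
#' @param calls cohort calls data.frame (>= 2 samples).
#' @param policy a `radmut_policy`.
#' @return list with `calls` (retained) and `removed`.
#' @export
filter_background <- function(calls, policy = filter_policy()) {
  if (length(unique(calls$sample_id)) < 2)
    stop("background filtering needs a cohort of at least 2 samples")
  key <- .site_key(calls)
  elig <- !is.na(calls$af) & calls$af > policy$cross_sample_max_af
  n_samples <- tapply(calls$sample_id[elig], key[elig],
                      function(x) length(unique(x)))
  bad <- names(n_samples)[n_samples > policy$background_max_samples]
  drop <- key %in% bad
  list(calls = calls[!drop, , drop = FALSE],
       removed = calls[drop, , drop = FALSE])
}

#' Assign zygosity with AF-band and cross-sample rules
#'
#' Applies, per call: exclusion at AF <= `af_exclude_max` (trace `low_af`);
#' exclusion when any other sample shows AF >= `cross_sample_max_af` at the
#' same site+allele (trace `cross_sample`); heterozygous for AF strictly
#' inside the het band; homozygous for AF >= `hom_min_af`; calls with no
#' usable depth are excluded with trace `no_depth`.  Calls falling in a
#' policy-created gap between the exclusion ceiling and the het band are
#' excluded with trace `af_gap` rather than silently dropped.
#'
#' @param calls cohort calls data.frame (post support filter).
#' @param policy a `radmut_policy`.
#' @return list with `calls` (retained, plus `zygosity` and `filter_trace`
#'   columns) and `excluded` (plus `filter_trace`).
#' @export
assign_zygosity <- function(calls, policy = filter_policy()) {
  n <- nrow(calls)
  if (n == 0) {
    calls$zygosity <- character(0)
    calls$filter_trace <- character(0)
    return(list(calls = calls, excluded = calls))
  }
  key <- .site_key(calls)
  # highest AF among *other* samples at the same site+allele
  other_max <- numeric(n)
  for (idx in split(seq_len(n), key)) {
    if (length(idx) == 1) next
    afs <- ifelse(is.na(calls$af[idx]), 0, calls$af[idx])
    for (j in seq_along(idx)) {
      others <- afs[-j][calls$sample_id[idx][-j] != calls$sample_id[idx][j]]
      other_max[idx[j]] <- if (length(others)) max(others) else 0
    }
  }
  af <- calls$af
  trace <- rep("pass", n)
  zyg <- rep(NA_character_, n)
  no_depth <- calls$depth <= 0 | is.na(af)
  trace[no_depth] <- "no_depth"
  low <- !no_depth & af <= policy$af_exclude_max
  trace[low] <- "low_af"
  cross <- !no_depth & !low & other_max >= policy$cross_sample_max_af
  trace[cross] <- "cross_sample"
  open <- !no_depth & !low & !cross
  het <- open & af > policy$het_min_af & af < policy$het_max_af
  hom <- open & af >= policy$hom_min_af
  gap <- open & !het & !hom
  trace[gap] <- "af_gap"
  zyg[het] <- "HET"
  zyg[hom] <- "HOM"
  calls$zygosity <- zyg
  calls$filter_trace <- trace
  keep <- het | hom
  list(calls = calls[keep, , drop = FALSE],
       excluded = calls[!keep, , drop = FALSE])
}

#' Full cohort filtering: support, background, zygosity
#'
#' Runs the three filtering stages in order and returns both the retained
#' calls (with zygosity) and an audit trail of everything excluded, tagged
#' with the rule that removed it.
#'
#' @param calls cohort calls data.frame.
#' @param policy a `radmut_policy`.
#' @return list with `calls` and `excluded` (audit data.frame with
#'   `filter_trace`).
#' @export
filter_calls <- function(calls, policy = filter_policy()) {
  supported <- apply_support_filter(calls, policy)
  low_support <- calls[!rownames(calls) %in% rownames(supported), ,
                       drop = FALSE]
  low_support$filter_trace <- rep("low_support", nrow(low_support))
  bg <- filter_background(supported, policy)
  bg$removed$filter_trace <- rep("background", nrow(bg$removed))
  zg <- assign_zygosity(bg$calls, policy)
  excl_cols <- function(d) {
    if (!"zygosity" %in% names(d))
      d$zygosity <- rep(NA_character_, nrow(d))
    d
  }
  excluded <- rbind(excl_cols(low_support), excl_cols(bg$removed),
                    zg$excluded)
  list(calls = zg$calls, excluded = excluded)
}

#' Write the exclusion audit trail
#' @param excluded excluded-calls data.frame from [filter_calls()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_audit <- function(excluded, path) {
  utils::write.table(excluded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
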