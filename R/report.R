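#' Run the full mutation-characterization pipeline
#'
#' Normalizes raw cohort calls against the reference, applies the support /
#' background / AF-band filters with zygosity assignment, merges proximal
#' calls into events with seven-category classification, and computes the
#' group summaries: category table, per-bp mutation frequency, substitution
#' spectrum and Ti/Tv, deletion size bins, het:hom ratios, sequence-context
#' annotation, gene impacts (when gene models are given) and pairwise group
#' comparisons.
#'
#' @param calls cohort calls data.frame (see [read_vcf_cohort()] or
#'   [emit_calls()]).
#' @param genome reference genome (`DNAStringSet`).
#' @param manifest data.frame (`sample_id`, `group`).
#' @param genes optional gene model data.frame for impact annotation.
#' @param policy a `radmut_policy`.
#' @param genome_length reference length used in MF denominators; defaults
#'   to the supplied genome's total length.
#' @param annotate run context annotation (default TRUE).
#' @param compare run pairwise group comparisons (default TRUE).
#' @return a `radmut_result` list; see the elements documented above.
#' @export
run_pipeline <- function(calls, genome, manifest, genes = NULL,
                         policy = filter_policy(), genome_length = NULL,
                         annotate = TRUE, compare = TRUE) {
  if (is.null(genome_length)) genome_length <- genome_length(genome)
  calls <- normalize_variants(calls, genome)
  flt <- filter_calls(calls, policy)
  events <- merge_events(flt$calls, policy)

  res <- list(calls = flt$calls, excluded = flt$excluded, events = events,
              manifest = manifest, policy = policy,
              genome_length = genome_length)
  res$categories <- summarize_categories(events, manifest)
  res$mf <- mutation_frequency(events, genome_length, manifest)
  res$het_hom <- het_hom_stats(events, manifest)

  groups <- unique(manifest$group)
  ev <- events
  ev$group <- manifest$group[match(ev$sample_id, manifest$sample_id)]
  res$spectrum <- lapply(stats::setNames(groups, groups), function(g)
    sbs_spectrum(ev[ev$group == g, , drop = FALSE]))
  del <- ev[ev$category %in% c("DEL1", "DEL_GE2"), , drop = FALSE]
  res$deletion_bins <- table(factor(del$group, levels = groups),
                             deletion_size_bin(del$net_length))

  if (annotate) {
    res$annotations <- annotate_events(events, genome)
    res$context_summary <- summarize_context(events, res$annotations,
                                             manifest)
  }
  if (!is.null(genes)) {
    res$impacts <- predict_effects(events, genes, genome)
    res$gene_counts <- count_affected_genes(res$impacts, manifest)
    res$functional_events <- proportion_functional_events(events,
                                                          res$impacts,
                                                          manifest)
  }
  if (compare && length(groups) >= 2)
    res$comparisons <- compare_groups(events, manifest, genome_length)
  class(res) <- "radmut_result"
  res
}

#' @export
print.radmut_result <- function(x, ...) {
  cat("radmut pipeline result\n")
  cat("  samples:", nrow(x$manifest),
      " groups:", length(unique(x$manifest$group)), "\n")
  cat("  events:", nrow(x$events),
      " (excluded calls:", nrow(x$excluded), ")\n")
  cat("  grand total (SV excluded):", x$categories$grand_total, "\n")
  g <- x$mf$group
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %s: %d events, MF %.2g /bp\n", g$group[i],
                g$total_events[i], g$mean_mf[i]))
  invisible(x)
}

.write_tsv <- function(d, path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write the report bundle
#'
#' Emits the pipeline's tables as TSV (events, excluded-call audit, category
#' counts and percentages, per-sample and group MF, spectrum, deletion size
#' bins, het:hom ratios, context summary, impacts and affected-gene counts
#' when present, pairwise comparisons) plus a JSON with the headline group
#' statistics and a run log.
#'
#' @param result a `radmut_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
build_report <- function(result, dir) {
  if (!inherits(result, "radmut_result"))
    stop("assembly error: expected a radmut_result from run_pipeline()")
  for (el in c("events", "categories", "mf", "het_hom"))
    if (is.null(result[[el]]))
      stop("assembly error: missing pipeline stage output: ", el)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$events, file.path(dir, "events.tsv"))
  .write_tsv(result$excluded, file.path(dir, "excluded_calls.tsv"))
  cts <- result$categories
  .write_tsv(data.frame(category = rownames(cts$counts), cts$counts,
                        check.names = FALSE),
             file.path(dir, "category_counts.tsv"))
  .write_tsv(data.frame(category = rownames(cts$percent_pooled),
                        cts$percent_pooled, check.names = FALSE),
             file.path(dir, "category_percent.tsv"))
  .write_tsv(result$mf$per_sample, file.path(dir, "mf_per_sample.tsv"))
  .write_tsv(result$mf$group, file.path(dir, "mf_group.tsv"))
  .write_tsv(result$het_hom$per_sample, file.path(dir, "het_hom.tsv"))
  .write_tsv(result$het_hom$group, file.path(dir, "het_hom_group.tsv"))
  sp <- do.call(rbind, lapply(names(result$spectrum), function(g)
    data.frame(group = g, t(result$spectrum[[g]]$spectrum),
               ti_tv = result$spectrum[[g]]$ti_tv, check.names = FALSE)))
  .write_tsv(sp, file.path(dir, "sbs_spectrum.tsv"))
  .write_tsv(as.data.frame.matrix(result$deletion_bins),
             file.path(dir, "deletion_bins.tsv"))
  if (!is.null(result$context_summary))
    .write_tsv(result$context_summary, file.path(dir, "context_summary.tsv"))
  if (!is.null(result$impacts)) {
    .write_tsv(result$impacts, file.path(dir, "impacts.tsv"))
    .write_tsv(result$gene_counts$per_sample,
               file.path(dir, "affected_genes_per_sample.tsv"))
    .write_tsv(result$gene_counts$group,
               file.path(dir, "affected_genes_group.tsv"))
  }
  if (!is.null(result$comparisons))
    .write_tsv(result$comparisons, file.path(dir, "comparisons.tsv"))

  headline <- list(
    grand_total = result$categories$grand_total,
    group_totals = as.list(result$categories$group_totals),
    mean_mf = stats::setNames(as.list(result$mf$group$mean_mf),
                              result$mf$group$group),
    ti_tv = lapply(result$spectrum, `[[`, "ti_tv"))
  jsonlite::write_json(headline, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("radmut version:",
                     as.character(utils::packageVersion("radmut"))),
               paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste("policy:", paste(names(result$policy),
                                      unlist(result$policy), sep = "=",
                                      collapse = " ")),
               paste("genome_length:", result$genome_length)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
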