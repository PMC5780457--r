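## Gene-impact prediction: which mutation events change protein sequence,
## and how many protein-coding genes are affected per sample.

.FUNCTIONAL_EFFECTS <- c("nonsynonymous", "frameshift", "stop_gain",
                         "stop_loss", "gene_deleted")

## per-gene summary: span, strand, translatability, cumulative CDS map
.gene_index <- function(genes) {
  ids <- unique(genes$gene_id)
  lapply(stats::setNames(ids, ids), function(gid) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    list(gene_id = gid, chrom = g$chrom[1], strand = g$strand[1],
         starts = g$start, ends = g$end,
         span = c(min(g$start), max(g$end)),
         translatable = all(g$translatable),
         cds_len = sum(g$end - g$start + 1L))
  })
}

## genomic position -> 1-based position in the plus-strand CDS concatenation
.cds_offset <- function(gi, pos) {
  off <- 0L
  for (k in seq_along(gi$starts)) {
    if (pos >= gi$starts[k] && pos <= gi$ends[k])
      return(off + pos - gi$starts[k] + 1L)
    off <- off + gi$ends[k] - gi$starts[k] + 1L
  }
  NA_integer_
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Predict gene-level effects of mutation events
#'
#' Substitutions inside a CDS are translated codon-wise on the gene's strand
#' and classified as synonymous, nonsynonymous, stop_gain or stop_loss.
#' Indels inside a CDS are frameshift when the net length is not a multiple
#' of three and nonsynonymous (in-frame) otherwise; a deletion whose
#' footprint spans a gene's entire CDS yields a `gene_deleted` record, one
#' per gene removed.  Events overlapping a gene outside its CDS are
#' `noncoding`; events overlapping no gene produce no record.  Genes flagged
#' non-translatable are skipped with a warning.
#'
#' @param events events data.frame from [merge_events()].
#' @param genes gene model data.frame.
#' @param genome reference genome.
#' @return impact data.frame: `event_id`, `sample_id`, `gene_id`, `effect`,
#'   `zygosity`.
#' @export
predict_effects <- function(events, genes, genome) {
  gidx <- .gene_index(genes)
  skipped <- names(gidx)[!vapply(gidx, `[[`, logical(1), "translatable")]
  if (length(skipped)) {
    warning("skipping non-translatable genes: ",
            paste(skipped, collapse = ", "))
    gidx <- gidx[setdiff(names(gidx), skipped)]
  }
  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (!exists(gid, envir = cds_cache, inherits = FALSE))
      assign(gid, cds_sequence(genes, genome, gid), envir = cds_cache)
    get(gid, envir = cds_cache, inherits = FALSE)
  }
  code <- Biostrings::GENETIC_CODE

  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    fp <- c(ev$start,
            if (ev$category == "SV" && !is.na(ev$sv_end)) ev$sv_end
            else ev$end)
    for (gi in gidx) {
      if (gi$chrom != ev$chrom || fp[1] > gi$span[2] || fp[2] < gi$span[1])
        next
      cds_ov <- any(fp[1] <= gi$ends & fp[2] >= gi$starts)
      is_del <- ev$category %in% c("DEL1", "DEL_GE2", "SV")
      effect <- if (is_del && fp[1] <= gi$span[1] && fp[2] >= gi$span[2]) {
        "gene_deleted"
      } else if (!cds_ov) {
        "noncoding"
      } else if (ev$category == "SBS") {
        cp <- .cds_offset(gi, ev$start)
        if (is.na(cp)) "noncoding" else {
          L <- gi$cds_len
          cds_pos <- if (gi$strand == "+") cp else L - cp + 1L
          base <- if (gi$strand == "+") ev$alt_allele
                  else .COMPLEMENT[[ev$alt_allele]]
          cds <- get_cds(gi$gene_id)
          ci <- (cds_pos - 1L) %/% 3L
          codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
          within <- cds_pos - 3L * ci
          new_codon <- codon
          substr(new_codon, within, within) <- base
          aa_old <- code[[codon]]
          aa_new <- code[[new_codon]]
          if (aa_old == aa_new) "synonymous"
          else if (aa_new == "*") "stop_gain"
          else if (aa_old == "*") "stop_loss"
          else "nonsynonymous"
        }
      } else if (ev$category == "INS1" || ev$category == "INS_GE2") {
        # insertion affects the CDS only if the insertion point lies
        # strictly inside a CDS interval
        inside <- any(ev$start >= gi$starts & ev$start < gi$ends)
        if (!inside) "noncoding"
        else if (ev$net_length %% 3L != 0L) "frameshift"
        else "nonsynonymous"
      } else {  # partial deletion or complex block
        if (is.na(ev$net_length) || ev$net_length %% 3L != 0L) "frameshift"
        else "nonsynonymous"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, sample_id = ev$sample_id,
        gene_id = gi$gene_id, effect = effect, zygosity = ev$zygosity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(event_id = character(), sample_id = character(),
                  gene_id = character(), effect = character(),
                  zygosity = character(), stringsAsFactors = FALSE)
}

#' Group mean and standard error
#' @param x numeric vector.
#' @return list with `mean` and `se` (sd / sqrt(n)).
#' @export
mean_se <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

#' Count protein-coding genes affected per sample and group
#'
#' A gene counts as affected when hit by at least one function-affecting
#' effect (nonsynonymous, frameshift, stop_gain, stop_loss, gene_deleted).
#' Each gene counts once per sample; a gene hit both heterozygously and
#' homozygously counts under the homozygous (stronger) state and is flagged.
#' Group summaries report mean +/- standard error (sd / sqrt(n samples)).
#'
#' @param impacts impact data.frame from [predict_effects()].
#' @param manifest data.frame (`sample_id`, `group`) covering every sample,
#'   including samples with no affected genes.
#' @return list with `per_sample` (columns `sample_id`, `group`, `hom`,
#'   `het`, `total`, `n_hom_het_conflict`) and `group` (mean/se per zygosity
#'   class).
#' @export
count_affected_genes <- function(impacts, manifest) {
  func <- impacts[impacts$effect %in% .FUNCTIONAL_EFFECTS, , drop = FALSE]
  per <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$sample_id[i]
    d <- func[func$sample_id == sid, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(sample_id = sid, group = manifest$group[i],
                        hom = 0L, het = 0L, total = 0L,
                        n_hom_het_conflict = 0L, stringsAsFactors = FALSE))
    zyg <- tapply(d$zygosity, d$gene_id,
                  function(z) if (any(z == "HOM")) "HOM" else "HET")
    conflict <- tapply(d$zygosity, d$gene_id,
                       function(z) length(unique(z)) > 1)
    data.frame(sample_id = sid, group = manifest$group[i],
               hom = sum(zyg == "HOM"), het = sum(zyg == "HET"),
               total = length(zyg),
               n_hom_het_conflict = sum(conflict),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  grp <- do.call(rbind, lapply(split(per, per$group), function(d) {
    h <- mean_se(d$hom); e <- mean_se(d$het); t <- mean_se(d$total)
    data.frame(group = d$group[1], n_samples = nrow(d),
               hom_total = sum(d$hom), hom_mean = h$mean, hom_se = h$se,
               het_total = sum(d$het), het_mean = e$mean, het_se = e$se,
               total = sum(d$total), total_mean = t$mean, total_se = t$se,
               stringsAsFactors = FALSE)
  }))
  rownames(grp) <- NULL
  list(per_sample = per, group = grp)
}

#' Proportion of mutation events with a function-affecting impact
#'
#' Event-level companion to [count_affected_genes()]: the fraction of
#' mutation events (SVs excluded) with at least one function-affecting
#' gene impact, per group.  Every event counts once however many genes it
#' hits, so a multi-gene deletion and a single nonsynonymous substitution
#' contribute equally here.
#'
#' @param events events data.frame.
#' @param impacts impact data.frame.
#' @param manifest data.frame (`sample_id`, `group`).
#' @return data.frame per group: `n_events`, `n_functional`, `proportion`.
#' @export
proportion_functional_events <- function(events, impacts, manifest) {
  ev <- events[events$category != "SV", , drop = FALSE]
  hit <- unique(impacts$event_id[impacts$effect %in% .FUNCTIONAL_EFFECTS])
  ev$group <- manifest$group[match(ev$sample_id, manifest$sample_id)]
  out <- do.call(rbind, lapply(split(ev, ev$group), function(d)
    data.frame(group = d$group[1], n_events = nrow(d),
               n_functional = sum(d$event_id %in% hit),
               proportion = sum(d$event_id %in% hit) / nrow(d),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
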