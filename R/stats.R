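## Group-level statistics: mutation frequency, substitution spectrum,
## zygosity ratios, group comparisons, derived rates and survival fitting.

#' Per-sample and group mutation frequency
#'
#' MF for a sample is its number of mutation events divided by the reference
#' genome length (events per bp); structural variants are excluded from the
#' count, and a complex event counts once regardless of its constituents.
#' The group mean over per-sample MFs equals total events / (n samples x L)
#' because all samples share the denominator.
#'
#' @param events events data.frame.
#' @param genome_length reference length L in bp (e.g. 119146348 for the
#'   TAIR10 nuclear genome).
#' @param manifest data.frame (`sample_id`, `group`) covering all samples.
#' @return list with `per_sample` (`sample_id`, `group`, `n_events`, `mf`)
#'   and `group` (`group`, `n_samples`, `total_events`, `mean_mf`, `se_mf`).
#' @export
mutation_frequency <- function(events, genome_length, manifest) {
  if (genome_length <= 0) stop("genome_length must be positive")
  ev <- events[events$category != "SV", , drop = FALSE]
  n <- vapply(manifest$sample_id,
              function(s) sum(ev$sample_id == s), numeric(1))
  per <- data.frame(sample_id = manifest$sample_id, group = manifest$group,
                    n_events = n, mf = n / genome_length,
                    stringsAsFactors = FALSE)
  grp <- do.call(rbind, lapply(split(per, per$group), function(d) {
    m <- mean_se(d$mf)
    data.frame(group = d$group[1], n_samples = nrow(d),
               total_events = sum(d$n_events),
               mean_mf = m$mean, se_mf = m$se, stringsAsFactors = FALSE)
  }))
  rownames(grp) <- NULL
  rownames(per) <- NULL
  list(per_sample = per, group = grp)
}

.SPECTRUM6 <- c("GC>AT", "AT>GC", "GC>TA", "GC>CG", "AT>TA", "AT>CG")

.sbs_class <- function(ref, alt) {
  key <- paste0(ref, alt)
  map <- c(GA = "GC>AT", CT = "GC>AT", AG = "AT>GC", TC = "AT>GC",
           GT = "GC>TA", CA = "GC>TA", GC = "GC>CG", CG = "GC>CG",
           AT = "AT>TA", TA = "AT>TA", AC = "AT>CG", TG = "AT>CG")
  unname(map[key])
}

#' Substitution spectrum with complementary classes merged
#'
#' Collapses the 12 directed single-base substitutions into the 6 classes
#' obtained by merging complementary changes (G>A with C>T, and so on), and
#' computes the transition/transversion ratio Ti/Tv, transitions being the
#' GC>AT and AT>GC classes.
#'
#' @param events events data.frame (only SBS rows are used).
#' @return list with `spectrum` (named counts over the 6 classes), `ti`,
#'   `tv`, `ti_tv`.
#' @export
sbs_spectrum <- function(events) {
  sbs <- events[events$category == "SBS", , drop = FALSE]
  cls <- .sbs_class(sbs$ref_allele, sbs$alt_allele)
  counts <- table(factor(cls, levels = .SPECTRUM6))
  ti <- sum(counts[c("GC>AT", "AT>GC")])
  tv <- sum(counts[c("GC>TA", "GC>CG", "AT>TA", "AT>CG")])
  list(spectrum = stats::setNames(as.integer(counts), .SPECTRUM6),
       ti = ti, tv = tv, ti_tv = if (tv > 0) ti / tv else NA_real_)
}

#' Category count and percentage table
#'
#' Given per-group event counts over the seven categories, reports per-group
#' totals, the grand total, and the percentage layout used for cohort
#' summaries: per-category percentages plus pooled Deletion (single-base +
#' multi-base) and Insertion percentages, rounded to integers.
#'
#' @param counts numeric matrix or data.frame, rows = categories (named
#'   `SBS`, `DEL1`, `DEL_GE2`, `INS1`, `INS_GE2`, `COMPLEX`, optionally
#'   `SV`), columns = groups.
#' @return list with `counts`, `group_totals`, `grand_total`, `percent`
#'   (per-category) and `percent_pooled` (rows SBS, Deletion, Insertion,
#'   Complex).
#' @export
category_table <- function(counts) {
  counts <- as.matrix(counts)
  core <- counts[setdiff(rownames(counts), "SV"), , drop = FALSE]
  totals <- colSums(core)
  pct <- function(m) round(100 * sweep(m, 2, totals, "/"))
  pooled <- rbind(SBS = core["SBS", ],
                  Deletion = core["DEL1", ] + core["DEL_GE2", ],
                  Insertion = core["INS1", ] + core["INS_GE2", ],
                  Complex = core["COMPLEX", ])
  colnames(pooled) <- colnames(core)
  list(counts = counts, group_totals = totals, grand_total = sum(totals),
       percent = pct(core), percent_pooled = pct(pooled))
}

#' Tabulate events into the category table
#' @param events events data.frame.
#' @param manifest data.frame (`sample_id`, `group`).
#' @return see [category_table()].
#' @export
summarize_categories <- function(events, manifest) {
  grp <- manifest$group[match(events$sample_id, manifest$sample_id)]
  tab <- table(factor(events$category, levels = .CATEGORIES),
               factor(grp, levels = unique(manifest$group)))
  category_table(unclass(tab))
}

#' Two-sample t-test on per-sample mutation frequencies
#'
#' Welch by default; set `var_equal = TRUE` for the pooled-variance test.
#' Degenerate input (both groups constant) yields `t = 0`, `p = 1` when the
#' means are equal and is otherwise reported as undefined.
#'
#' @param x,y per-sample MF vectors.
#' @param var_equal pooled-variance flag.
#' @return list with `t`, `df`, `p`, `note`.
#' @export
mf_ttest <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = NA_real_, p = 1, note = "zero variance"))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                note = "zero variance, unequal means"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, note = "")
}

#' Chi-squared homogeneity test on a contingency table
#'
#' Pearson chi-squared without continuity correction; when any expected
#' count is below 5 the result carries a warning note (the statistic is
#' still reported).
#'
#' @param tab counts matrix (groups x classes).
#' @return list with `statistic`, `df`, `p`, `note`.
#' @export
chisq_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2 || nrow(tab) < 2 || any(rowSums(tab) == 0))
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                note = "degenerate table"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  note <- if (any(ct$expected < 5)) "expected count < 5" else ""
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, note = note)
}

#' Pairwise group comparisons
#'
#' For every pair of groups: a t-test on per-sample MFs and chi-squared
#' homogeneity tests on the category counts, the merged substitution
#' spectrum, and the deletion size bins.
#'
#' @param events events data.frame.
#' @param manifest data.frame (`sample_id`, `group`).
#' @param genome_length reference length in bp.
#' @param var_equal passed to [mf_ttest()].
#' @return data.frame with one row per group pair.
#' @export
compare_groups <- function(events, manifest, genome_length,
                           var_equal = FALSE) {
  mf <- mutation_frequency(events, genome_length, manifest)
  groups <- unique(manifest$group)
  ev <- events[events$category != "SV", , drop = FALSE]
  ev$group <- manifest$group[match(ev$sample_id, manifest$sample_id)]
  rows <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    a <- groups[i]; b <- groups[j]
    tt <- mf_ttest(mf$per_sample$mf[mf$per_sample$group == a],
                   mf$per_sample$mf[mf$per_sample$group == b],
                   var_equal = var_equal)
    pair <- ev[ev$group %in% c(a, b), , drop = FALSE]
    cat_tab <- table(pair$group, factor(pair$category,
                                        levels = setdiff(.CATEGORIES, "SV")))
    sp <- rbind(sbs_spectrum(pair[pair$group == a, ])$spectrum,
                sbs_spectrum(pair[pair$group == b, ])$spectrum)
    del <- pair[pair$category %in% c("DEL1", "DEL_GE2"), , drop = FALSE]
    del_tab <- table(factor(del$group, levels = c(a, b)),
                     deletion_size_bin(del$net_length))
    ch_cat <- chisq_homogeneity(cat_tab)
    ch_sp <- chisq_homogeneity(sp)
    ch_del <- chisq_homogeneity(del_tab)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = a, group_b = b,
      mf_t = tt$t, mf_p = tt$p,
      category_chisq = ch_cat$statistic, category_p = ch_cat$p,
      spectrum_chisq = ch_sp$statistic, spectrum_p = ch_sp$p,
      delsize_chisq = ch_del$statistic, delsize_p = ch_del$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heterozygous:homozygous ratios per sample and group
#'
#' Per-sample het/hom ratio of retained mutation events (SVs excluded); a
#' sample with zero homozygous events has an undefined ratio and is flagged
#' and excluded from the group mean.  The group mean of defined ratios is
#' tested against the Mendelian M2 expectation of 2.0 with a one-sample
#' t-test.
#'
#' @param events events data.frame.
#' @param manifest data.frame (`sample_id`, `group`).
#' @param expected expected ratio (default 2).
#' @return list with `per_sample`, `group` (mean/se of defined ratios plus
#'   `t_vs_expected`, `p_vs_expected`), and `expected`.
#' @export
het_hom_stats <- function(events, manifest, expected = 2) {
  ev <- events[events$category != "SV", , drop = FALSE]
  per <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$sample_id[i]
    d <- ev[ev$sample_id == sid, , drop = FALSE]
    het <- sum(d$zygosity == "HET"); hom <- sum(d$zygosity == "HOM")
    data.frame(sample_id = sid, group = manifest$group[i],
               het = het, hom = hom,
               ratio = if (hom > 0) het / hom else NA_real_,
               undefined_ratio = hom == 0, stringsAsFactors = FALSE)
  }))
  grp <- do.call(rbind, lapply(split(per, per$group), function(d) {
    r <- d$ratio[!is.na(d$ratio)]
    m <- mean_se(r)
    tt <- if (length(r) >= 2 && stats::sd(r) > 0)
      stats::t.test(r, mu = expected) else NULL
    data.frame(group = d$group[1], n_defined = length(r),
               n_undefined = sum(d$undefined_ratio),
               mean_ratio = m$mean, se_ratio = m$se,
               t_vs_expected = if (is.null(tt)) NA_real_
                               else unname(tt$statistic),
               p_vs_expected = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(grp) <- NULL
  list(per_sample = per, group = grp, expected = expected)
}

#' Simulated Mendelian het:hom expectation
#'
#' Draws `n` independent segregating mutations, each homozygous with
#' probability 1/3 and heterozygous with probability 2/3 (1:2:1 segregation
#' with the homozygous wild type undetectable), and returns the observed
#' het:hom ratio; the analytic limit is 2.0.
#'
#' @param n number of mutations (>= 1).
#' @param seed integer seed, or `NULL`.
#' @return list with `het`, `hom`, `ratio` (`Inf` when hom = 0).
#' @export
mendelian_expectation <- function(n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  hom <- stats::rbinom(1, n, 1 / 3)
  het <- n - hom
  list(het = het, hom = hom,
       ratio = if (hom > 0) het / hom else Inf)
}

#' Derived mutation rates: M1 extrapolation and fold over spontaneous
#'
#' Under Mendelian inheritance an M2 plant carries 3/4 of the mutations of
#' its M1 parent (the homozygous wild-type quarter of each segregating locus
#' is lost), so the M1 frequency is 4/3 times the M2 estimate.  The fold
#' change is reported against a spontaneous per-bp frequency.
#'
#' @param mf_m2 per-bp mutation frequency estimated in M2.
#' @param spontaneous spontaneous per-bp frequency (default 7.1e-9).
#' @return list with `mf_m2`, `mf_m1`, `fold_over_spontaneous`,
#'   `spontaneous_mf`.
#' @export
derived_rates <- function(mf_m2, spontaneous = 7.1e-9) {
  if (mf_m2 < 0) stop("mf_m2 must be >= 0")
  if (spontaneous <= 0) stop("spontaneous must be positive")
  mf_m1 <- 4 / 3 * mf_m2
  list(mf_m2 = mf_m2, mf_m1 = mf_m1,
       fold_over_spontaneous = mf_m1 / spontaneous,
       spontaneous_mf = spontaneous)
}

#' Per-locus mutation frequency from a phenotype screen
#'
#' Per-locus MF = mutants / (plants x loci); scaled by the number of
#' protein-coding genes in the genome it gives the expected number of genes
#' per plant carrying a homozygous loss-of-function mutation.
#'
#' @param mutant_count observed mutants.
#' @param n_plants screened plants.
#' @param n_loci scored loci.
#' @param n_genes_genome protein-coding genes in the genome (default 27206).
#' @return list with `per_locus_mf` and `expected_genes_per_plant`.
#' @export
locus_mf <- function(mutant_count, n_plants, n_loci,
                     n_genes_genome = 27206) {
  if (n_plants <= 0 || n_loci <= 0 || n_genes_genome <= 0)
    stop("denominators must be positive")
  per_locus <- mutant_count / (n_plants * n_loci)
  list(per_locus_mf = per_locus,
       expected_genes_per_plant = per_locus * n_genes_genome)
}

#' Single-hit multitarget survival fraction
#'
#' S(D) = 1 - (1 - exp(-D / D0))^n, the classic multitarget model: each of
#' `n` targets is inactivated exponentially with mean lethal dose `D0`, and
#' the cell survives until all targets are hit.  The quasi-threshold
#' shoulder dose is Dq = D0 ln n.
#'
#' @param dose dose (Gy).
#' @param D0 mean lethal dose (Gy), > 0.
#' @param n extrapolation number, >= 1.
#' @return survival fraction in \[0, 1\].
#' @export
survival_fraction <- function(dose, D0, n) {
  1 - (1 - exp(-dose / D0))^n
}

#' Fit the single-hit multitarget survival model
#'
#' Least-squares fit of S(D) = 1 - (1 - exp(-D/D0))^n over D0 > 0, n >= 1,
#' via Levenberg-Marquardt with a log-linear tail fit for starting values
#' (at high dose ln S ~ ln n - D/D0) and a fallback start grid.  Returns
#' the shoulder dose Dq = D0 ln n.
#'
#' @param dose doses (Gy), at least 3 points including 0.
#' @param survival survival fractions in \[0, 1\], ~1 at dose 0.
#' @return list with `D0`, `n`, `Dq`, and the `nls` fit object.
#' @export
fit_survival <- function(dose, survival) {
  if (length(dose) != length(survival) || length(dose) < 3)
    stop("need >= 3 (dose, survival) points")
  if (!any(dose == 0)) stop("dose points must include 0")
  if (any(survival < 0 | survival > 1))
    stop("survival fractions must be in [0, 1]")
  if (all(survival > 0.99))
    stop("no dose response: survival is ~1 at every dose")

  d <- data.frame(dose = dose, s = survival)
  tail <- d[d$dose > 0 & d$s > 0 & d$s < 0.8, , drop = FALSE]
  starts <- list()
  if (nrow(tail) >= 2) {
    lf <- stats::lm(log(s) ~ dose, data = tail)
    sl <- stats::coef(lf)[2]
    if (is.finite(sl) && sl < 0)
      starts[[1]] <- list(D0 = unname(-1 / sl),
                          n = max(1, unname(exp(stats::coef(lf)[1]))))
  }
  dmax <- max(d$dose)
  for (D0g in dmax * c(0.05, 0.15, 0.4))
    for (ng in c(1, 2, 5, 20, 100))
      starts[[length(starts) + 1L]] <- list(D0 = D0g, n = ng)

  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ 1 - (1 - exp(-dose / D0))^n, data = d,
                        start = st, lower = c(D0 = 1e-9, n = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("survival fit did not converge; tried ", length(starts),
         " starting points")
  cf <- stats::coef(fit)
  list(D0 = unname(cf["D0"]), n = unname(cf["n"]),
       Dq = unname(cf["D0"] * log(cf["n"])), fit = fit)
}
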