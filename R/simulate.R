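## Synthetic mutagenesis cohorts: ground-truth mutations with the category,
## context and segregation structure the downstream analysis assumes, plus
## noisy per-sample call sets.

.CATEGORIES <- c("SBS", "DEL1", "DEL_GE2", "INS1", "INS_GE2", "COMPLEX", "SV")
.SBS_CLASSES <- c("GC>AT", "AT>GC", "GC>TA", "GC>CG", "AT>TA", "AT>CG")

#' Define a simulation profile for one experimental group
#'
#' The per-sample expected event counts, context biases and noise levels
#' define the study conditions a group emulates.  Zygosity mode
#' `"mendelian_m2"` retains each mutation as homozygous with probability 1/3
#' and heterozygous with probability 2/3, i.e. 1:2:1 segregation of an M1
#' heterozygous mutation with the homozygous wild type undetectable.
#'
#' @param group_name group label.
#' @param n_samples number of M2 samples in the group.
#' @param events_per_sample named numeric vector of expected event counts per
#'   sample over categories `SBS, DEL1, DEL_GE2, INS1, INS_GE2, COMPLEX, SV`
#'   (missing categories default to 0).
#' @param zygosity_mode one of `"mendelian_m2"`, `"fixed_het"`, `"fixed_hom"`.
#' @param context_bias named list of planting fractions in \[0,1\]:
#'   `homopolymer_fraction_for_del1`, `homopolymer_fraction_for_ins1`,
#'   `repeat_or_microhomology_fraction_for_del_ge2`,
#'   `repeat_or_microhomology_fraction_for_ins_ge2`.
#' @param deletion_size_weights weights over multi-bp deletion size bins
#'   `2-9`, `10-49`, `>=50`.
#' @param sbs_weights weights over the six complementary-merged substitution
#'   classes `GC>AT, AT>GC, GC>TA, GC>CG, AT>TA, AT>CG`.
#' @param noise list: `false_positive_low_af_rate` (expected low-AF false
#'   positives per sample, planted at AF <= 0.25),
#'   `false_positive_near_af_rate` (planted at AF in (0.25, 0.30\]),
#'   `n_background_sites_shared` (sites injected into > 2 samples),
#'   `depth_mean` (mean sequencing depth, >= 10).
#' @return an object of class `radmut_profile`.
#' @export
simulation_profile <- function(group_name,
                               n_samples = 6L,
                               events_per_sample = c(SBS = 12),
                               zygosity_mode = c("mendelian_m2", "fixed_het",
                                                 "fixed_hom"),
                               context_bias = list(),
                               deletion_size_weights = c(`2-9` = 0.6,
                                                         `10-49` = 0.3,
                                                         `>=50` = 0.1),
                               sbs_weights = c(0.32, 0.10, 0.14,
                                               0.08, 0.24, 0.12),
                               noise = list()) {
  zygosity_mode <- match.arg(zygosity_mode)
  if (n_samples < 1) stop("n_samples must be >= 1")
  events_per_sample <- unlist(events_per_sample)
  deletion_size_weights <- unlist(deletion_size_weights)
  sbs_weights <- unlist(sbs_weights)
  ev <- stats::setNames(numeric(length(.CATEGORIES)), .CATEGORIES)
  if (!all(names(events_per_sample) %in% .CATEGORIES))
    stop("unknown category in events_per_sample")
  ev[names(events_per_sample)] <- events_per_sample
  if (any(ev < 0)) stop("expected event counts must be >= 0")

  cb <- list(homopolymer_fraction_for_del1 = 0.45,
             homopolymer_fraction_for_ins1 = 0.45,
             repeat_or_microhomology_fraction_for_del_ge2 = 0.49,
             repeat_or_microhomology_fraction_for_ins_ge2 = 0.76)
  cb[names(context_bias)] <- context_bias
  if (any(unlist(cb) < 0 | unlist(cb) > 1))
    stop("context_bias fractions must be in [0, 1]")

  nz <- list(false_positive_low_af_rate = 0,
             false_positive_near_af_rate = 0,
             n_background_sites_shared = 0L,
             depth_mean = 30)
  nz[names(noise)] <- noise
  if (nz$depth_mean < 10) stop("depth_mean must be >= 10")

  if (length(deletion_size_weights) != 3 || any(deletion_size_weights < 0))
    stop("deletion_size_weights must be 3 non-negative weights")
  names(deletion_size_weights) <- c("2-9", "10-49", ">=50")
  if (length(sbs_weights) != 6 || any(sbs_weights < 0))
    stop("sbs_weights must be 6 non-negative weights")

  structure(list(group_name = group_name, n_samples = as.integer(n_samples),
                 events_per_sample = ev, zygosity_mode = zygosity_mode,
                 context_bias = cb,
                 deletion_size_weights =
                   deletion_size_weights / sum(deletion_size_weights),
                 sbs_weights = sbs_weights / sum(sbs_weights),
                 noise = nz),
            class = "radmut_profile")
}

#' Built-in group profiles
#'
#' Ready-made profiles emulating a dry-seed-irradiated or a
#' seedling-irradiated M2 group of six plants: per-sample expected category
#' counts, deletion-size mix, substitution-class mix and context-planting
#' fractions follow the cohort-level characteristics of carbon-ion
#' mutagenesis (higher indel load and smaller repeat/microhomology share in
#' large deletions for dry seeds; SBS-dominated spectra for seedlings).
#'
#' @param dose dose label selecting one of the two calibrations per material.
#' @param noise noise list passed to [simulation_profile()].
#' @return a `radmut_profile`.
#' @export
dry_seed_profile <- function(dose = c("125", "175"), noise = list()) {
  dose <- match.arg(dose)
  ev <- if (dose == "125")
    c(SBS = 72, DEL1 = 23, DEL_GE2 = 68, INS1 = 8, INS_GE2 = 5,
      COMPLEX = 14) / 6
  else
    c(SBS = 98, DEL1 = 28, DEL_GE2 = 70, INS1 = 8, INS_GE2 = 8,
      COMPLEX = 16) / 6
  simulation_profile(
    group_name = paste0("dry", dose), events_per_sample = ev,
    zygosity_mode = "mendelian_m2",
    context_bias = list(homopolymer_fraction_for_del1 = 22 / 49,
                        homopolymer_fraction_for_ins1 = 8 / 18,
                        repeat_or_microhomology_fraction_for_del_ge2 = 63 / 129,
                        repeat_or_microhomology_fraction_for_ins_ge2 = 13 / 17),
    deletion_size_weights = c(`2-9` = 80, `10-49` = 40, `>=50` = 9),
    sbs_weights = c(0.32, 0.10, 0.14, 0.08, 0.24, 0.12),
    noise = noise)
}

#' @rdname dry_seed_profile
#' @export
seedling_profile <- function(dose = c("20", "30"), noise = list()) {
  dose <- match.arg(dose)
  ev <- if (dose == "20")
    c(SBS = 78, DEL1 = 9, DEL_GE2 = 27, INS1 = 2, INS_GE2 = 1,
      COMPLEX = 15) / 6
  else
    c(SBS = 72, DEL1 = 8, DEL_GE2 = 21, INS1 = 2, INS_GE2 = 3,
      COMPLEX = 11) / 6
  simulation_profile(
    group_name = paste0("seedling", dose), events_per_sample = ev,
    zygosity_mode = "mendelian_m2",
    context_bias = list(homopolymer_fraction_for_del1 = 8 / 16,
                        homopolymer_fraction_for_ins1 = 8 / 18,
                        repeat_or_microhomology_fraction_for_del_ge2 = 19 / 44,
                        repeat_or_microhomology_fraction_for_ins_ge2 = 13 / 17),
    deletion_size_weights = c(`2-9` = 19, `10-49` = 19, `>=50` = 6),
    sbs_weights = c(0.34, 0.11, 0.20, 0.10, 0.10, 0.15),
    noise = noise)
}

#' Simulate ground-truth mutations for one or more groups
#'
#' Places mutation events on the reference with the category counts, sequence
#' contexts and zygosity segregation requested by the profiles.  Events are
#' kept mutually isolated (footprints at least ~55 bp apart across the whole
#' cohort) except for the constituents of COMPLEX events, so that merged and
#' isolated events are unambiguous in recovery tests.  COMPLEX events are
#' emitted as multiple constituent rows sharing an `event_id` (either two
#' adjacent substitutions, or a substitution plus a nearby short deletion
#' separated by a gap of 2-8 reference bases).
#'
#' @param genome a `DNAStringSet` genome.
#' @param profiles a `radmut_profile` or list of them.
#' @param seed integer seed, or `NULL`.
#' @return truth data.frame, one row per constituent call: `group`,
#'   `sample_id`, `event_id`, `chrom`, `pos` (1-based; first changed base for
#'   substitutions, first deleted base for deletions, anchor base preceding
#'   the insertion for insertions), `category`, `ref_seg`, `alt_seg`,
#'   `zygosity`, `planted_context`, `sv_end`.
#' @export
simulate_mutations <- function(genome, profiles, seed = NULL) {
  if (inherits(profiles, "radmut_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "radmut_profile")))
  if (!is.null(seed)) set.seed(seed)

  chrs <- names(genome)
  chars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  widths <- Biostrings::width(genome)
  names(widths) <- chrs
  mask <- lapply(widths, logical)

  runs <- do.call(rbind, lapply(chrs, function(cc) {
    r <- .seq_runs(as.character(genome[[cc]]))
    r$chrom <- cc
    r
  }))
  runs3 <- runs[runs$length >= 3, , drop = FALSE]
  runs2 <- runs[runs$length >= 2, , drop = FALSE]

  is_free <- function(cc, lo, hi) {
    lo <- max(1L, lo); hi <- min(widths[[cc]], hi)
    !any(mask[[cc]][lo:hi])
  }
  block <- function(cc, lo, hi) {
    lo <- max(1L, lo - 2L); hi <- min(widths[[cc]], hi + 2L)
    mask[[cc]][lo:hi] <<- TRUE
  }
  # random free site whose footprint [pos, pos + span - 1] keeps >= ~55 bp
  # clearance from every previously placed footprint
  rand_site <- function(span) {
    for (i in 1:5000) {
      cc <- sample(chrs, 1, prob = widths)
      w <- widths[[cc]]
      if (w < span + 40L) next
      pos <- sample.int(w - span - 30L, 1) + 15L
      if (is_free(cc, pos - 60L, pos + span + 59L))
        return(list(chrom = cc, pos = pos))
    }
    stop("genome capacity exhausted while placing mutations")
  }
  ch <- function(cc, i, j = i) paste(chars[[cc]][i:j], collapse = "")

  pick_run <- function(tab, min_len = 3L) {
    idx <- sample.int(nrow(tab))
    for (i in idx) {
      cc <- tab$chrom[i]; s <- tab$start[i]; l <- tab$length[i]
      if (s > 15L && s + l + 15L < widths[[cc]] &&
          is_free(cc, s - 60L, s + l + 59L))
        return(tab[i, , drop = FALSE])
    }
    NULL
  }

  class_ref <- list("GC>AT" = c(G = "A", C = "T"),
                    "AT>GC" = c(A = "G", T = "C"),
                    "GC>TA" = c(G = "T", C = "A"),
                    "GC>CG" = c(G = "C", C = "G"),
                    "AT>TA" = c(A = "T", T = "A"),
                    "AT>CG" = c(A = "C", T = "G"))

  out <- list(); n_out <- 0L
  push <- function(row) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- row
  }
  row_df <- function(sample_id, group, event_id, cc, pos, category,
                     ref_seg, alt_seg, zyg, context, sv_end = NA_integer_)
    list(group = group, sample_id = sample_id, event_id = event_id,
         chrom = cc, pos = as.integer(pos), category = category,
         ref_seg = ref_seg, alt_seg = alt_seg, zygosity = zyg,
         planted_context = context, sv_end = as.integer(sv_end))

  for (prof in profiles) {
    for (si in seq_len(prof$n_samples)) {
      sid <- paste0(prof$group_name, "-", si)
      ev_n <- 0L
      zyg_draw <- function() switch(prof$zygosity_mode,
        mendelian_m2 = if (stats::runif(1) < 1 / 3) "HOM" else "HET",
        fixed_het = "HET", fixed_hom = "HOM")
      new_id <- function() {
        ev_n <<- ev_n + 1L
        sprintf("%s:e%03d", sid, ev_n)
      }

      for (cat in .CATEGORIES) {
        lam <- prof$events_per_sample[[cat]]
        n <- if (lam > 0) stats::rpois(1, lam) else 0L
        if (n == 0L) next
        if (cat == "SV" && genome_length(genome) < 1e4)
          stop("SV events need a genome of at least 10 kb (capacity error)")
        for (k in seq_len(n)) {
          zyg <- zyg_draw()
          id <- new_id()
          switch(cat,
            SBS = {
              cls <- sample(.SBS_CLASSES, 1, prob = prof$sbs_weights)
              map <- class_ref[[cls]]
              repeat {
                s <- rand_site(1L)
                b <- chars[[s$chrom]][s$pos]
                if (b %in% names(map)) break
              }
              push(row_df(sid, prof$group_name, id, s$chrom, s$pos, "SBS",
                          b, unname(map[[b]]), zyg, "none"))
              block(s$chrom, s$pos, s$pos)
            },
            DEL1 = {
              planted <- stats::runif(1) <
                prof$context_bias$homopolymer_fraction_for_del1
              if (planted) {
                r <- pick_run(runs3)
                if (is.null(r)) stop("no free homopolymer run >= 3 left")
                push(row_df(sid, prof$group_name, id, r$chrom, r$start,
                            "DEL1", r$base, "", zyg, "homopolymer"))
                block(r$chrom, r$start, r$start + r$length - 1L)
              } else {
                repeat {
                  s <- rand_site(1L)
                  v <- chars[[s$chrom]]
                  if (v[s$pos - 1L] != v[s$pos] && v[s$pos + 1L] != v[s$pos])
                    break
                }
                push(row_df(sid, prof$group_name, id, s$chrom, s$pos, "DEL1",
                            chars[[s$chrom]][s$pos], "", zyg, "none"))
                block(s$chrom, s$pos, s$pos)
              }
            },
            DEL_GE2 = {
              bin <- sample(names(prof$deletion_size_weights), 1,
                            prob = prof$deletion_size_weights)
              size <- switch(bin,
                             "2-9" = sample(2:9, 1),
                             "10-49" = sample(10:49, 1),
                             ">=50" = round(exp(stats::runif(1, log(50),
                                                             log(2000)))))
              planted <- stats::runif(1) <
                prof$context_bias$repeat_or_microhomology_fraction_for_del_ge2
              placed <- FALSE
              if (planted && size <= 6 && stats::runif(1) < 0.5) {
                # delete one copy of an exact tandem repeat
                for (t in 1:400) {
                  s <- rand_site(2L * size)
                  v <- chars[[s$chrom]]
                  u <- v[s$pos:(s$pos + size - 1L)]
                  if (.is_uniform(u)) next
                  if (identical(u, v[(s$pos + size):(s$pos + 2L * size - 1L)])) {
                    push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                                "DEL_GE2", paste(u, collapse = ""), "",
                                zyg, "repeat"))
                    block(s$chrom, s$pos, s$pos + 2L * size - 1L)
                    placed <- TRUE
                    break
                  }
                }
              }
              if (planted && !placed) {
                # junction microhomology: deleted prefix equals retained
                # downstream flank prefix (>= 2 bp survives at the junction)
                for (t in 1:1000) {
                  s <- rand_site(size + 2L)
                  v <- chars[[s$chrom]]
                  d <- v[s$pos:(s$pos + size - 1L)]
                  if (.is_uniform(d)) next
                  if (v[s$pos] == v[s$pos + size] &&
                      v[s$pos + 1L] == v[s$pos + size + 1L]) {
                    push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                                "DEL_GE2", paste(d, collapse = ""), "",
                                zyg, "microhomology"))
                    block(s$chrom, s$pos, s$pos + size - 1L)
                    placed <- TRUE
                    break
                  }
                }
                if (!placed) stop("could not plant microhomology context")
              }
              if (!planted) {
                for (t in 1:600) {
                  s <- rand_site(size)
                  v <- chars[[s$chrom]]
                  d <- v[s$pos:(s$pos + size - 1L)]
                  if (.is_uniform(d)) next
                  D <- paste(d, collapse = "")
                  U <- ch(s$chrom, max(1L, s$pos - 10L), s$pos - 1L)
                  W <- ch(s$chrom, s$pos + size,
                          min(widths[[s$chrom]], s$pos + size + 9L))
                  # suffix homology 0 keeps the placement left-aligned, so
                  # the junction is exactly what the detectors will see
                  if (.common_suffix_len(U, D) >= 1L ||
                      .common_prefix_len(D, W) >= 2L) next
                  jrep <- function(j) {
                    lo <- max(1L, j - 11L)
                    !is.na(.tandem_at_boundary(
                      ch(s$chrom, lo, min(widths[[s$chrom]], j + 12L)),
                      j - lo + 1L))
                  }
                  if (jrep(s$pos - 1L) || jrep(s$pos + size - 1L)) next
                  push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                              "DEL_GE2", D, "", zyg, "none"))
                  block(s$chrom, s$pos, s$pos + size - 1L)
                  placed <- TRUE
                  break
                }
                if (!placed) stop("could not place context-free deletion")
              }
            },
            INS1 = {
              planted <- stats::runif(1) <
                prof$context_bias$homopolymer_fraction_for_ins1
              if (planted) {
                r <- pick_run(runs2)
                if (is.null(r)) stop("no free run >= 2 left for insertion")
                push(row_df(sid, prof$group_name, id, r$chrom, r$start,
                            "INS1", "", r$base, zyg, "homopolymer"))
                block(r$chrom, r$start, r$start + r$length - 1L)
              } else {
                repeat {
                  s <- rand_site(2L)
                  v <- chars[[s$chrom]]
                  b <- sample(setdiff(c("A", "C", "G", "T"),
                                      c(v[s$pos], v[s$pos + 1L])), 1)
                  break
                }
                push(row_df(sid, prof$group_name, id, s$chrom, s$pos, "INS1",
                            "", b, zyg, "none"))
                block(s$chrom, s$pos, s$pos + 1L)
              }
            },
            INS_GE2 = {
              planted <- stats::runif(1) <
                prof$context_bias$repeat_or_microhomology_fraction_for_ins_ge2
              if (planted && stats::runif(1) < 0.5) {
                # tandem duplication of the 2-3 bases preceding the anchor
                repeat {
                  u <- sample(2:3, 1)
                  s <- rand_site(u + 1L)
                  v <- chars[[s$chrom]]
                  anchor <- s$pos + u - 1L
                  unit <- v[s$pos:anchor]
                  if (!.is_uniform(unit)) break
                }
                push(row_df(sid, prof$group_name, id, s$chrom, anchor,
                            "INS_GE2", "", paste(unit, collapse = ""),
                            zyg, "repeat"))
                block(s$chrom, s$pos, anchor + 1L)
              } else if (planted) {
                # inserted sequence shares a >= 2 bp prefix with the
                # downstream flank (microhomology at the rejoined site)
                repeat {
                  size <- sample(2:9, 1)
                  s <- rand_site(size + 2L)
                  v <- chars[[s$chrom]]
                  if (v[s$pos + 1L] == v[s$pos + 2L]) next
                  ins <- c(v[s$pos + 1L], v[s$pos + 2L],
                           if (size > 2) sample(c("A", "C", "G", "T"),
                                                size - 2L, replace = TRUE))
                  if (!.is_uniform(ins)) break
                }
                push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                            "INS_GE2", "", paste(ins, collapse = ""),
                            zyg, "microhomology"))
                block(s$chrom, s$pos, s$pos + 1L)
              } else {
                placed <- FALSE
                for (t in 1:600) {
                  size <- sample(2:9, 1)
                  s <- rand_site(size + 2L)
                  v <- chars[[s$chrom]]
                  ins <- sample(c("A", "C", "G", "T"), size, replace = TRUE)
                  if (.is_uniform(ins)) next
                  D <- paste(ins, collapse = "")
                  U <- ch(s$chrom, max(1L, s$pos - 9L), s$pos)
                  W <- ch(s$chrom, s$pos + 1L,
                          min(widths[[s$chrom]], s$pos + 10L))
                  if (.common_suffix_len(U, D) >= 1L ||
                      .common_prefix_len(D, W) >= 2L) next
                  lw <- ch(s$chrom, max(1L, s$pos - 12L), s$pos)
                  rw <- ch(s$chrom, s$pos + 1L,
                           min(widths[[s$chrom]], s$pos + 12L))
                  win <- paste0(lw, D, rw)
                  if (.has_tandem_overlap(win, nchar(lw),
                                          nchar(lw) + size + 1L)) next
                  push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                              "INS_GE2", "", D, zyg, "none"))
                  block(s$chrom, s$pos, s$pos + 1L)
                  placed <- TRUE
                  break
                }
                if (!placed) stop("could not place context-free insertion")
              }
            },
            COMPLEX = {
              if (stats::runif(1) < 0.6) {
                # two immediately consecutive substitutions
                s <- rand_site(2L)
                v <- chars[[s$chrom]]
                for (j in 0:1) {
                  b <- v[s$pos + j]
                  push(row_df(sid, prof$group_name, id, s$chrom, s$pos + j,
                              "COMPLEX", b,
                              sample(setdiff(c("A", "C", "G", "T"), b), 1),
                              zyg, "none"))
                }
                block(s$chrom, s$pos, s$pos + 1L)
              } else {
                # substitution plus nearby short deletion, gap 2-8 bases
                gap <- sample(2:8, 1)
                dsz <- sample(2:4, 1)
                span <- 1L + gap + dsz
                s <- rand_site(span)
                v <- chars[[s$chrom]]
                b <- v[s$pos]
                push(row_df(sid, prof$group_name, id, s$chrom, s$pos,
                            "COMPLEX", b,
                            sample(setdiff(c("A", "C", "G", "T"), b), 1),
                            zyg, "none"))
                ds <- s$pos + 1L + gap
                push(row_df(sid, prof$group_name, id, s$chrom, ds, "COMPLEX",
                            ch(s$chrom, ds, ds + dsz - 1L), "", zyg, "none"))
                block(s$chrom, s$pos, s$pos + span - 1L)
              }
            },
            SV = {
              size <- sample(3000:8000, 1)
              s <- rand_site(size)
              push(row_df(sid, prof$group_name, id, s$chrom, s$pos, "SV",
                          "", "<DEL>", zyg, "none",
                          sv_end = s$pos + size - 1L))
              block(s$chrom, s$pos, s$pos + size - 1L)
            })
        }
      }
    }
  }
  if (n_out == 0L)
    return(data.frame(group = character(), sample_id = character(),
                      event_id = character(), chrom = character(),
                      pos = integer(), category = character(),
                      ref_seg = character(), alt_seg = character(),
                      zygosity = character(), planted_context = character(),
                      sv_end = integer(), stringsAsFactors = FALSE))
  out <- out[seq_len(n_out)]
  truth <- data.frame(
    group = vapply(out, `[[`, character(1), "group"),
    sample_id = vapply(out, `[[`, character(1), "sample_id"),
    event_id = vapply(out, `[[`, character(1), "event_id"),
    chrom = vapply(out, `[[`, character(1), "chrom"),
    pos = vapply(out, `[[`, integer(1), "pos"),
    category = vapply(out, `[[`, character(1), "category"),
    ref_seg = vapply(out, `[[`, character(1), "ref_seg"),
    alt_seg = vapply(out, `[[`, character(1), "alt_seg"),
    zygosity = vapply(out, `[[`, character(1), "zygosity"),
    planted_context = vapply(out, `[[`, character(1), "planted_context"),
    sv_end = vapply(out, `[[`, integer(1), "sv_end"),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$sample_id, truth$chrom, truth$pos), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  truth
}

#' Emit noisy per-sample variant calls from ground truth
#'
#' Converts each truth constituent into a VCF-anchored call with read counts:
#' depth is Poisson around `depth_mean` (floored at 10), mutant reads are
#' binomial with success probability 0.5 for heterozygous and 0.98 for
#' homozygous mutations (the 0.98 emulates residual sequencing error so the
#' AF >= 0.8 homozygous rule stays meaningful).  Low-AF false positives
#' (AF <= 0.25, >= 3 mutant reads), optional near-threshold false positives
#' (AF in (0.25, 0.30]), and background artifact sites shared by more than
#' two samples are injected per the noise profile.
#'
#' @param truth truth data.frame from [simulate_mutations()].
#' @param genome the `DNAStringSet` genome the truth was simulated on.
#' @param manifest data.frame with columns `sample_id`, `group` listing every
#'   sample (including samples without events).
#' @param noise noise list (see [simulation_profile()]).
#' @param seed integer seed, or `NULL`.
#' @param out_dir if non-`NULL`, per-sample VCF 4.2 files plus `truth.tsv`
#'   and `manifest.tsv` are written there.
#' @return calls data.frame: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `mutant_reads`, `depth`, `af`, `origin` (`truth`/`fp`/`background`),
#'   `event_id`, `sv_end`.
#' @export
emit_calls <- function(truth, genome, manifest,
                       noise = list(), seed = NULL, out_dir = NULL) {
  nz <- list(false_positive_low_af_rate = 0,
             false_positive_near_af_rate = 0,
             n_background_sites_shared = 0L, depth_mean = 30)
  nz[names(noise)] <- noise
  if (nz$depth_mean < 10) stop("depth_mean must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  widths <- Biostrings::width(genome)
  names(widths) <- names(genome)

  rows <- list()
  if (nrow(truth) > 0) {
    seqs <- vapply(as.character(unique(truth$chrom)), function(cc)
      as.character(genome[[cc]]), character(1))
    base_at <- function(cc, p) substr(seqs[[cc]], p, p)
    n <- nrow(truth)
    pos <- integer(n); ref <- character(n); alt <- character(n)
    sv_end <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (truth$alt_seg[i] == "<DEL>") {
        pos[i] <- truth$pos[i]
        ref[i] <- base_at(truth$chrom[i], truth$pos[i])
        alt[i] <- "<DEL>"
        sv_end[i] <- truth$sv_end[i]
      } else if (nzchar(truth$ref_seg[i]) && !nzchar(truth$alt_seg[i])) {
        a <- base_at(truth$chrom[i], truth$pos[i] - 1L)      # deletion
        pos[i] <- truth$pos[i] - 1L
        ref[i] <- paste0(a, truth$ref_seg[i])
        alt[i] <- a
      } else if (!nzchar(truth$ref_seg[i])) {                # insertion
        a <- base_at(truth$chrom[i], truth$pos[i])
        pos[i] <- truth$pos[i]
        ref[i] <- a
        alt[i] <- paste0(a, truth$alt_seg[i])
      } else {                                               # substitution
        pos[i] <- truth$pos[i]
        ref[i] <- truth$ref_seg[i]
        alt[i] <- truth$alt_seg[i]
      }
    }
    depth <- pmax(10L, stats::rpois(n, nz$depth_mean))
    pr <- ifelse(truth$zygosity == "HET", 0.5, 0.98)
    mut <- stats::rbinom(n, depth, pr)
    rows[[1]] <- data.frame(
      sample_id = truth$sample_id, chrom = truth$chrom,
      pos = pos, ref = ref, alt = alt,
      mutant_reads = mut, depth = depth, af = mut / depth,
      origin = "truth", event_id = truth$event_id,
      sv_end = sv_end, stringsAsFactors = FALSE)
  }

  rand_fp_site <- function() {
    cc <- sample(names(genome), 1, prob = widths)
    pos <- sample.int(widths[[cc]] - 32L, 1) + 16L
    list(chrom = cc, pos = pos)
  }
  fp_row <- function(sid, af_lo, af_hi) {
    s <- rand_fp_site()
    d <- max(16L, stats::rpois(1, nz$depth_mean))
    m_lo <- max(3L, floor(af_lo * d) + 1L)
    m_hi <- floor(af_hi * d)
    if (m_hi < m_lo) { d <- 20L; m_lo <- max(3L, floor(af_lo * d) + 1L)
                       m_hi <- floor(af_hi * d) }
    m <- if (m_lo == m_hi) m_lo else sample(m_lo:m_hi, 1)
    b <- genome_slice(genome, s$chrom, s$pos, s$pos)
    if (stats::runif(1) < 0.7) {           # low-AF substitution artifact
      data.frame(sample_id = sid, chrom = s$chrom, pos = s$pos, ref = b,
                 alt = sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 mutant_reads = m, depth = d, af = m / d, origin = "fp",
                 event_id = NA_character_, sv_end = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {                               # low-AF 1-bp deletion artifact
      data.frame(sample_id = sid, chrom = s$chrom, pos = s$pos,
                 ref = paste0(b, genome_slice(genome, s$chrom, s$pos + 1L,
                                              s$pos + 1L)),
                 alt = b, mutant_reads = m, depth = d, af = m / d,
                 origin = "fp", event_id = NA_character_,
                 sv_end = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  for (sid in manifest$sample_id) {
    n_fp <- stats::rpois(1, nz$false_positive_low_af_rate)
    for (k in seq_len(n_fp))
      rows[[length(rows) + 1L]] <- fp_row(sid, 0, 0.25)
    n_near <- stats::rpois(1, nz$false_positive_near_af_rate)
    for (k in seq_len(n_near))
      rows[[length(rows) + 1L]] <- fp_row(sid, 0.25, 0.30)
  }

  n_samp <- nrow(manifest)
  if (nz$n_background_sites_shared > 0 && n_samp >= 3) {
    for (k in seq_len(nz$n_background_sites_shared)) {
      s <- rand_fp_site()
      b <- genome_slice(genome, s$chrom, s$pos, s$pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      n_in <- sample(3:n_samp, 1)
      for (sid in sample(manifest$sample_id, n_in)) {
        d <- pmax(10L, stats::rpois(1, nz$depth_mean))
        m <- max(3L, stats::rbinom(1, d, 0.5))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, chrom = s$chrom, pos = s$pos, ref = b, alt = alt,
          mutant_reads = m, depth = d, af = m / d, origin = "background",
          event_id = NA_character_, sv_end = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }

  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), mutant_reads = integer(),
               depth = integer(), af = numeric(), origin = character(),
               event_id = character(), sv_end = integer(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos), ,
                 drop = FALSE]
  rownames(calls) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in manifest$sample_id)
      write_vcf(calls[calls$sample_id == sid, , drop = FALSE], genome,
                file.path(out_dir, paste0(sid, ".vcf")), sample_id = sid)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  calls
}

#' Simulate a complete cohort (genome, genes, truth, calls)
#'
#' Convenience orchestration: generates a reference with gene models, plants
#' ground-truth mutations per the group profiles, and emits noisy per-sample
#' calls.  All randomness flows from the single `seed`.
#'
#' @param profiles a `radmut_profile` or list of them.
#' @param seed integer seed.
#' @param genome,genes optional pre-built genome and gene models (both or
#'   neither); when `NULL` they are generated.
#' @param genome_length,n_chromosomes,gc_fraction,homopolymer_enrichment
#'   passed to [generate_reference()].
#' @param n_genes,cds_length_codons passed to [generate_gene_models()].
#' @param out_dir if non-`NULL`, FASTA, GFF3, VCFs, truth and manifest are
#'   written there.
#' @return list with `genome`, `genes`, `truth`, `calls`, `manifest`.
#' @export
simulate_cohort <- function(profiles, seed = 1L, genome = NULL, genes = NULL,
                            genome_length = 5e5, n_chromosomes = 2L,
                            gc_fraction = 0.36, homopolymer_enrichment = 1,
                            n_genes = 60L, cds_length_codons = c(60L, 200L),
                            out_dir = NULL) {
  if (inherits(profiles, "radmut_profile")) profiles <- list(profiles)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  if (is.null(genome)) {
    genome <- generate_reference(genome_length, n_chromosomes, gc_fraction,
                                 homopolymer_enrichment, seed = seeds[1])
    gm <- generate_gene_models(genome, n_genes, cds_length_codons,
                               seed = seeds[2])
    genome <- gm$genome
    genes <- gm$genes
  }
  truth <- simulate_mutations(genome, profiles, seed = seeds[3])
  manifest <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = paste0(p$group_name, "-", seq_len(p$n_samples)),
               group = p$group_name, stringsAsFactors = FALSE)))
  # cohort-wide noise taken from the first profile (backgrounds are shared
  # across all samples, as in a jointly processed sequencing batch)
  calls <- emit_calls(truth, genome, manifest, noise = profiles[[1]]$noise,
                      seed = seeds[4], out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_genome_fasta(genome, file.path(out_dir, "reference.fasta"))
    if (!is.null(genes)) write_gff3(genes, file.path(out_dir, "genes.gff3"))
  }
  list(genome = genome, genes = genes, truth = truth, calls = calls,
       manifest = manifest)
}

#' Read a simulation profile from a YAML or JSON file
#' @param path config file with fields matching [simulation_profile()].
#' @return a `radmut_profile`.
#' @export
read_profile <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(simulation_profile, cfg)
}
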