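test_that("mutation frequency agrees computed both ways", {
  counts <- c(a1 = 30, a2 = 35, a3 = 25, b1 = 10, b2 = 20, b3 = 15)
  manifest <- data.frame(sample_id = names(counts),
                         group = rep(c("A", "B"), each = 3))
  ev <- make_sample_events(counts)
  L <- 1e6
  mf <- mutation_frequency(ev, L, manifest)
  expect_equal(mf$per_sample$mf, unname(counts) / L)
  a <- mf$group[mf$group$group == "A", ]
  expect_equal(a$mean_mf, a$total_events / (a$n_samples * L))
  expect_error(mutation_frequency(ev, 0, manifest), "positive")
})

test_that("SV events are excluded from mutation frequency", {
  manifest <- data.frame(sample_id = "s1", group = "g")
  ev <- rbind(make_event("SBS", "chr1", 10L, 10L),
              make_event("SV", "chr1", 100L, 5000L, sv_end = 5000L,
                         net_length = 0L))
  mf <- mutation_frequency(ev, 1e6, manifest)
  expect_equal(mf$per_sample$n_events, 1)
})

test_that("spectrum merges complementary substitutions and derives Ti/Tv", {
  mk <- function(ref, alt, pos) {
    ev <- make_event("SBS", "chr1", pos, pos, net_length = 0L)
    ev$ref_allele <- ref
    ev$alt_allele <- alt
    ev
  }
  ev <- rbind(mk("C", "T", 10L), mk("G", "A", 20L))
  sp <- sbs_spectrum(ev)
  expect_equal(unname(sp$spectrum["GC>AT"]), 2L)
  expect_equal(sum(sp$spectrum), 2L)

  # equal counts in all six classes: Ti/Tv = 2/4
  ev6 <- rbind(mk("G", "A", 1L), mk("A", "G", 2L), mk("G", "T", 3L),
               mk("G", "C", 4L), mk("A", "T", 5L), mk("A", "C", 6L))
  expect_equal(sbs_spectrum(ev6)$ti_tv, 0.5)
})

test_that("spectrum operation matches a direct per-pair tally", {
  set.seed(91)
  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, 500, replace = TRUE)
  alts <- vapply(refs, function(b) sample(setdiff(bases, b), 1), "")
  ev <- do.call(rbind, lapply(1:500, function(i) {
    e <- make_event("SBS", "chr1", i * 10L, i * 10L, net_length = 0L)
    e$ref_allele <- refs[i]
    e$alt_allele <- alts[i]
    e
  }))
  sp <- sbs_spectrum(ev)
  # oracle: explicit complementing and tallying
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  canon <- ifelse(refs %in% c("G", "C"),
                  paste0(ifelse(refs == "G", refs, comp[refs]), ">",
                         ifelse(refs == "G", alts, comp[alts])),
                  paste0(ifelse(refs == "A", refs, comp[refs]), ">",
                         ifelse(refs == "A", alts, comp[alts])))
  oracle <- c("GC>AT" = sum(canon == "G>A"), "AT>GC" = sum(canon == "A>G"),
              "GC>TA" = sum(canon == "G>T"), "GC>CG" = sum(canon == "G>C"),
              "AT>TA" = sum(canon == "A>T"), "AT>CG" = sum(canon == "A>C"))
  expect_equal(sp$spectrum[names(oracle)], oracle)
  expect_equal(sp$ti_tv, unname((oracle[1] + oracle[2]) /
                                sum(oracle[3:6])))
})

test_that("degenerate and textbook comparison cases behave", {
  out <- mf_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # identical row proportions: statistic 0
  tab <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chisq_homogeneity(tab)$statistic, 0)
  # 2x2 closed form: all expected counts are 15
  tab2 <- rbind(c(10, 20), c(20, 10))
  o <- c(10, 20, 20, 10)
  expect_equal(chisq_homogeneity(tab2)$statistic,
               sum((o - 15)^2 / 15))
  # Welch t on a 3-point toy input against the closed form
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  se2 <- stats::var(x) / 3 + stats::var(y) / 3
  expect_equal(mf_ttest(x, y)$t, (mean(x) - mean(y)) / sqrt(se2))
})

test_that("het:hom ratios flag undefined samples and test against 2", {
  ev1 <- make_sample_events(c(s1 = 30), "SBS")
  ev1$zygosity <- rep(c("HET", "HOM"), times = c(20, 10))
  ev2 <- make_sample_events(c(s2 = 33), "SBS")   # all heterozygous
  manifest <- data.frame(sample_id = c("s1", "s2"), group = "g")
  hh <- het_hom_stats(rbind(ev1, ev2), manifest)
  s1 <- hh$per_sample[hh$per_sample$sample_id == "s1", ]
  expect_equal(s1$ratio, 2)            # 20 het / 10 hom
  s2 <- hh$per_sample[hh$per_sample$sample_id == "s2", ]
  expect_true(s2$undefined_ratio)      # hom = 0: ratio undefined, flagged
  expect_true(is.na(s2$ratio))
  expect_equal(hh$group$n_undefined, 1L)
  expect_equal(hh$group$mean_ratio, 2) # mean over defined ratios only
})

test_that("simulated Mendelian ratios approach 2.0", {
  m <- mendelian_expectation(1e5, seed = 92)
  expect_gt(m$ratio, 1.9)
  expect_lt(m$ratio, 2.1)
  expect_equal(m$het + m$hom, 1e5)
  m1 <- mendelian_expectation(1, seed = 92)
  expect_true(m1$ratio %in% c(0, Inf))
  expect_error(mendelian_expectation(0), ">= 1")
})

test_that("derived rates apply the 4/3 M1 extrapolation", {
  r <- derived_rates(3e-7)
  expect_equal(r$mf_m1, 4e-7)
  expect_equal(r$fold_over_spontaneous, 4e-7 / 7.1e-9)
  r0 <- derived_rates(0)
  expect_equal(r0$mf_m1, 0)
  expect_equal(r0$fold_over_spontaneous, 0)
  expect_error(derived_rates(1e-7, spontaneous = 0), "positive")
})

test_that("per-locus MF arithmetic holds on identity denominators", {
  out <- locus_mf(1, 1, 1, n_genes_genome = 10)
  expect_equal(out$per_locus_mf, 1)
  expect_equal(out$expected_genes_per_plant, 10)
  out0 <- locus_mf(0, 100, 10, 1000)
  expect_equal(out0$per_locus_mf, 0)
  expect_error(locus_mf(1, 0, 1, 1), "positive")
})

test_that("survival fit recovers parameters from noise-free curves", {
  dose <- seq(0, 400, by = 40)
  s <- survival_fraction(dose, D0 = 80, n = 20)
  fit <- fit_survival(dose, s)
  expect_lt(abs(fit$Dq - 80 * log(20)) / (80 * log(20)), 0.01)
  # pure exponential: no shoulder
  s1 <- survival_fraction(dose, D0 = 60, n = 1)
  fit1 <- fit_survival(dose, s1)
  expect_lt(fit1$Dq, 2)
  expect_error(fit_survival(dose, rep(1, length(dose))), "no dose response")
  expect_error(fit_survival(c(10, 20, 30), c(0.9, 0.5, 0.2)), "include 0")
})

test_that("survival Dq recovery stays within 5% under 1% noise", {
  set.seed(93)
  errs <- c()
  for (D0 in c(40, 80, 160)) for (n in c(3, 10, 40)) {
    dose <- seq(0, 5 * D0, length.out = 12)
    s <- pmin(1, pmax(0, survival_fraction(dose, D0, n) +
                           stats::rnorm(12, 0, 0.01)))
    s[1] <- 1
    fit <- fit_survival(dose, s)
    dq <- D0 * log(n)
    errs <- c(errs, abs(fit$Dq - dq) / dq)
  }
  expect_lt(stats::median(errs), 0.05)
})

test_that("category table pools deletions/insertions and excludes SV", {
  counts <- matrix(c(10, 5, 5, 2, 2, 6, 3), ncol = 1,
                   dimnames = list(c("SBS", "DEL1", "DEL_GE2", "INS1",
                                     "INS_GE2", "COMPLEX", "SV"), "g"))
  ct <- category_table(counts)
  expect_equal(ct$grand_total, 30)     # SV row not in totals
  expect_equal(unname(ct$percent_pooled["Deletion", 1]), 33)
  expect_equal(unname(ct$percent_pooled["Insertion", 1]), 13)
  expect_equal(unname(ct$percent_pooled["SBS", 1]), 33)
})
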