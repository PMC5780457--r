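test_that("generated reference hits requested length and GC content", {
  g <- generate_reference(1e5, 2, 0.36, 0, seed = 1)
  expect_equal(genome_length(g), 1e5)
  expect_equal(length(g), 2L)
  gc <- sum(Biostrings::letterFrequency(g, "GC")) / genome_length(g)
  expect_lt(abs(gc - 0.36), 0.02)
  expect_error(generate_reference(0, 1, 0.5, 0, seed = 1), "10 kb")
  expect_error(generate_reference(1e5, 1, 1.2, 0, seed = 1), "gc_fraction")
})

test_that("homopolymer enrichment raises run density over the iid genome", {
  g0 <- generate_reference(1e5, 2, 0.36, 0, seed = 1)
  g5 <- generate_reference(1e5, 2, 0.36, 5, seed = 1)
  runs0 <- sum(vapply(as.character(g0), scan_runs_ge, numeric(1)))
  runs5 <- sum(vapply(as.character(g5), scan_runs_ge, numeric(1)))
  expect_gt(runs5, runs0)
})

test_that("gene models are translatable, non-overlapping and in-frame", {
  g <- generate_reference(1e5, 2, 0.4, 0, seed = 2)
  gm <- generate_gene_models(g, 20, c(50, 100), seed = 2)
  genes <- gm$genes
  expect_equal(length(unique(genes$gene_id)), 20L)
  # CDS length divisible by 3 per gene
  lens <- tapply(genes$end - genes$start + 1L, genes$gene_id, sum)
  expect_true(all(lens %% 3 == 0))
  # intervals non-overlapping within each chromosome
  for (cc in unique(genes$chrom)) {
    iv <- genes[genes$chrom == cc, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  }
  # every gene translates from its own strand with no internal stop
  for (gid in unique(genes$gene_id)) {
    cds <- cds_sequence(genes, gm$genome, gid)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("gene placement fails on an overfull genome", {
  small <- as_genome(c(chr1 = random_seq(1000, seed = 3)))
  expect_error(generate_gene_models(small, 500, c(50, 100), seed = 3),
               "capacity")
})

test_that("Mendelian M2 segregation gives a pooled het:hom ratio near 2", {
  g <- generate_reference(6e5, 2, 0.36, 0.5, seed = 4)
  prof <- simulation_profile("m2", n_samples = 6,
                             events_per_sample = c(SBS = 300),
                             zygosity_mode = "mendelian_m2")
  truth <- simulate_mutations(g, prof, seed = 4)
  expect_gt(nrow(truth), 1500)
  ratio <- sum(truth$zygosity == "HET") / sum(truth$zygosity == "HOM")
  # binomial oracle: n ~ 1800, p(het) = 2/3, +/- 2 sd band around 2.0
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("planted DEL1 homopolymer context is real in the reference", {
  g <- generate_reference(2e5, 1, 0.36, 1, seed = 5)
  prof <- simulation_profile(
    "hp", n_samples = 2, events_per_sample = c(DEL1 = 30),
    context_bias = list(homopolymer_fraction_for_del1 = 1.0))
  truth <- simulate_mutations(g, prof, seed = 5)
  expect_true(all(truth$planted_context == "homopolymer"))
  s <- as.character(g[[1]])
  for (i in seq_len(nrow(truth))) {
    b <- truth$ref_seg[i]
    p <- truth$pos[i]
    run <- 1L
    while (substr(s, p - 1, p - 1) == b) { run <- run + 1L; p <- p - 1L }
    p <- truth$pos[i]
    while (substr(s, p + 1, p + 1) == b) { run <- run + 1L; p <- p + 1L }
    expect_gte(run, 3L)
  }
})

test_that("all-zero expected counts give an empty truth set", {
  g <- generate_reference(2e4, 1, 0.4, 0, seed = 6)
  prof <- simulation_profile("empty", n_samples = 3,
                             events_per_sample = c(SBS = 0))
  truth <- simulate_mutations(g, prof, seed = 6)
  expect_equal(nrow(truth), 0L)
})

test_that("emitted HET calls have binomial AF centred at 0.5", {
  g <- generate_reference(5e5, 1, 0.4, 0, seed = 7)
  prof <- simulation_profile("het", n_samples = 2,
                             events_per_sample = c(SBS = 500),
                             zygosity_mode = "fixed_het")
  truth <- simulate_mutations(g, prof, seed = 7)
  manifest <- data.frame(sample_id = c("het-1", "het-2"), group = "het")
  calls <- emit_calls(truth, g, manifest,
                      noise = list(depth_mean = 30), seed = 7)
  expect_equal(nrow(calls), nrow(truth))
  expect_gt(mean(calls$af), 0.45)
  expect_lt(mean(calls$af), 0.55)
})

test_that("with zero noise, calls biject with truth records", {
  g <- generate_reference(1e5, 1, 0.4, 0.5, seed = 8)
  prof <- simulation_profile("nn", n_samples = 3,
                             events_per_sample = c(SBS = 10, DEL1 = 5,
                                                   DEL_GE2 = 5, INS1 = 3,
                                                   INS_GE2 = 3, COMPLEX = 2))
  truth <- simulate_mutations(g, prof, seed = 8)
  manifest <- data.frame(sample_id = paste0("nn-", 1:3), group = "nn")
  calls <- emit_calls(truth, g, manifest, noise = list(), seed = 8)
  expect_equal(nrow(calls), nrow(truth))
  expect_setequal(calls$event_id, truth$event_id)
  expect_true(all(calls$origin == "truth"))
})

test_that("identical seeds reproduce byte-identical truth tables and VCFs", {
  prof <- dry_seed_profile("125",
                           noise = list(false_positive_low_af_rate = 1,
                                        n_background_sites_shared = 2,
                                        depth_mean = 30))
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_cohort(prof, seed = 99, genome_length = 1e5, n_genes = 10,
                        out_dir = d1)
  s2 <- simulate_cohort(prof, seed = 99, genome_length = 1e5, n_genes = 10,
                        out_dir = d2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$calls, s2$calls)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("profile validation rejects bad inputs", {
  expect_error(simulation_profile("x", n_samples = 0), "n_samples")
  expect_error(simulation_profile("x", events_per_sample = c(SBS = -1)),
               ">= 0")
  expect_error(simulation_profile("x",
                                  context_bias =
                                    list(homopolymer_fraction_for_del1 = 2)),
               "\\[0, 1\\]")
  expect_error(simulation_profile("x", noise = list(depth_mean = 5)),
               "depth_mean")
  expect_error(simulation_profile("x", events_per_sample = c(FOO = 1)),
               "unknown category")
})
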