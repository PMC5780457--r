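test_that("FASTA reading truncates headers, rejects duplicates, round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">chr1 assembly=test", "ACGT"), f)
  g <- read_genome_fasta(f)
  expect_identical(names(g), "chr1")
  expect_equal(genome_length(g), 4)
  expect_identical(genome_slice(g, "chr1", 1, 4), "ACGT")

  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), f)
  expect_error(read_genome_fasta(f), "duplicate")

  g0 <- generate_reference(1e4, 2, 0.4, 1, seed = 1)
  write_genome_fasta(g0, f)
  g1 <- read_genome_fasta(f)
  expect_identical(as.character(g1), as.character(g0))
  unlink(f)
})

test_that("VCF records parse into calls with AD-derived AF", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "plantA", sep = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:10,20:30",
    "chr1\t200\t.\tA\tT,C\t.\tPASS\t.\tGT:AD:DP\t1/2:5,10,15:30"), f)
  calls <- read_vcf_calls(f)
  expect_equal(nrow(calls), 3L)
  expect_identical(calls$sample_id[1], "plantA")
  one <- calls[calls$pos == 100, ]
  expect_equal(one$mutant_reads, 20L)
  expect_equal(one$depth, 30L)
  expect_equal(one$af, 20 / 30)
  # multi-allelic record split into one call per alternate allele
  multi <- calls[calls$pos == 200, ]
  expect_identical(multi$alt, c("T", "C"))
  expect_equal(multi$mutant_reads, c(10L, 15L))
  unlink(f)
})

test_that("empty VCF body yields an empty call set", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "plantA", sep = "\t")), f)
  calls <- suppressWarnings(read_vcf_calls(f))
  expect_equal(nrow(calls), 0L)
  unlink(f)
})

test_that("simulate -> write VCF -> read reproduces the call set exactly", {
  prof <- simulation_profile("rt", n_samples = 2,
                             events_per_sample = c(SBS = 8, DEL1 = 4,
                                                   DEL_GE2 = 4, INS_GE2 = 2),
                             noise = list(false_positive_low_af_rate = 1,
                                          depth_mean = 30))
  dir <- file.path(tempdir(), "rtsim")
  sim <- simulate_cohort(prof, seed = 21, genome_length = 1e5, n_genes = 5,
                         out_dir = dir)
  for (sid in sim$manifest$sample_id) {
    back <- read_vcf_calls(file.path(dir, paste0(sid, ".vcf")))
    orig <- sim$calls[sim$calls$sample_id == sid, ]
    orig <- orig[order(orig$chrom, orig$pos), ]
    expect_equal(back$pos, orig$pos)
    expect_identical(back$ref, orig$ref)
    expect_identical(back$alt, orig$alt)
    expect_equal(back$mutant_reads, orig$mutant_reads)
    expect_equal(back$depth, orig$depth)
    expect_equal(back$af, orig$af)
  }
  unlink(dir, recursive = TRUE)
})

test_that("indels are left-aligned to the run start", {
  #            1234567890
  g <- as_genome(c(chr1 = "GGCAAAATGG"))
  # deletion of the *last* A of the AAAA run, right-aligned representation
  call <- make_calls("s1", "chr1", 6L, "AA", "A")
  nn <- normalize_variants(call, g)
  # exhaustive-shift oracle: deleting any A of the run gives the same
  # haplotype; the leftmost deleted base is position 4, anchor position 3
  expect_equal(nn$pos, 3L)
  expect_identical(nn$ref, "CA")
  expect_identical(nn$alt, "C")

  # same variant expressed with trailing context trims to the same thing
  call2 <- make_calls("s1", "chr1", 5L, "AAT", "AT")
  nn2 <- normalize_variants(call2, g)
  expect_identical(nn2[c("pos", "ref", "alt")], nn[c("pos", "ref", "alt")])

  # insertion of an A into the run left-aligns to the run start
  ins <- make_calls("s1", "chr1", 7L, "A", "AA")
  ni <- normalize_variants(ins, g)
  expect_equal(ni$pos, 3L)
  expect_identical(ni$ref, "C")
  expect_identical(ni$alt, "CA")
})

test_that("normalization is idempotent and net-length preserving", {
  g <- as_genome(c(chr1 = random_seq(500, seed = 31)))
  s <- as.character(g[[1]])
  set.seed(31)
  rows <- lapply(1:40, function(i) {
    p <- sample(20:450, 1)
    len <- sample(1:6, 1)
    if (runif(1) < 0.5) {
      make_calls("s1", "chr1", p, substr(s, p, p + len), substr(s, p, p))
    } else {
      make_calls("s1", "chr1", p, substr(s, p, p),
                 paste0(substr(s, p, p), random_seq(len)))
    }
  })
  calls <- do.call(rbind, rows)
  n1 <- normalize_variants(calls, g)
  n2 <- normalize_variants(n1, g)
  expect_identical(n1, n2)
  expect_equal(nchar(n1$alt) - nchar(n1$ref),
               nchar(calls$alt) - nchar(calls$ref))
  # SNVs pass through unchanged
  snv <- make_calls("s1", "chr1", 50L, substr(s, 50, 50),
                    setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1])
  expect_identical(normalize_variants(snv, g), snv)
})

test_that("GFF3 gene models round-trip through write and read", {
  g <- generate_reference(5e4, 1, 0.4, 0, seed = 41)
  gm <- generate_gene_models(g, 8, c(50, 80), two_exon_fraction = 0.5,
                             seed = 41)
  f <- tempfile(fileext = ".gff3")
  write_gff3(gm$genes, f)
  back <- read_gff3(f)
  a <- gm$genes[order(gm$genes$gene_id, gm$genes$start),
                c("gene_id", "chrom", "strand", "start", "end")]
  b <- back[order(back$gene_id, back$start),
            c("gene_id", "chrom", "strand", "start", "end")]
  rownames(a) <- rownames(b) <- NULL
  b$gene_id <- sub("\\.1$", "", b$gene_id)  # parent resolution keeps gene ID
  expect_equal(a, b)
  expect_true(all(back$translatable))
  unlink(f)
})

test_that("transposable-element genes and pseudogenes are skipped", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t163\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t101\t163\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tx\tCDS\t101\t130\t.\t+\t0\tID=cA1;Parent=gA.1",
    "chr1\tx\tCDS\t131\t163\t.\t+\t0\tID=cA2;Parent=gA.1",
    "chr1\tx\ttransposable_element_gene\t201\t260\t.\t-\t.\tID=gTE",
    "chr1\tx\tmRNA\t201\t260\t.\t-\t.\tID=gTE.1;Parent=gTE",
    "chr1\tx\tCDS\t201\t260\t.\t-\t0\tID=cTE;Parent=gTE.1",
    "chr1\tx\tpseudogene\t301\t360\t.\t+\t.\tID=gPS",
    "chr1\tx\tmRNA\t301\t360\t.\t+\t.\tID=gPS.1;Parent=gPS",
    "chr1\tx\tCDS\t301\t360\t.\t+\t0\tID=cPS;Parent=gPS.1"), f)
  genes <- read_gff3(f)
  expect_identical(unique(genes$gene_id), "gA")
  expect_equal(sum(genes$end - genes$start + 1L), 63L)  # 30 + 33 bp
  unlink(f)
})

test_that("empty GFF3 yields an empty gene set", {
  f <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  expect_equal(nrow(read_gff3(f)), 0L)
  unlink(f)
})

test_that("profiles and policies load from YAML config files", {
  pf <- tempfile(fileext = ".yaml")
  writeLines(c("group_name: demo",
               "n_samples: 3",
               "events_per_sample:",
               "  SBS: 10",
               "  DEL1: 2",
               "zygosity_mode: mendelian_m2",
               "noise:",
               "  depth_mean: 25"), pf)
  prof <- read_profile(pf)
  expect_s3_class(prof, "radmut_profile")
  expect_equal(prof$n_samples, 3L)
  expect_equal(unname(prof$events_per_sample["SBS"]), 10)
  expect_equal(prof$noise$depth_mean, 25)

  pl <- tempfile(fileext = ".yaml")
  writeLines(c("min_mutant_reads: 4", "hom_min_af: 0.85"), pl)
  pol <- read_policy(pl)
  expect_equal(pol$min_mutant_reads, 4L)
  expect_equal(pol$hom_min_af, 0.85)
  expect_equal(pol$af_exclude_max, 0.25)
  unlink(c(pf, pl))
})
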