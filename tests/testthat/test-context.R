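test_that("homopolymer detection counts the run including flanks", {
  #               1234567890
  g <- as_genome(c(chr1 = "TTCAAAATGC"))
  # delete one A out of the AAAA run (left-aligned first A at 4)
  ev <- make_event("DEL1", "chr1", 4L, 4L, deleted_seq = "A")
  hp <- detect_homopolymer(g, ev)
  expect_true(hp$flag)
  expect_identical(hp$base, "A")
  expect_equal(hp$run, 4L)

  # isolated base: run of 1
  g2 <- as_genome(c(chr1 = "TTGCACGTTT"))
  ev2 <- make_event("DEL1", "chr1", 5L, 5L, deleted_seq = "A")
  hp2 <- detect_homopolymer(g2, ev2)
  expect_false(hp2$flag)
  expect_equal(hp2$run, 1L)

  # insertion of A next to AA: post-insertion run of 3
  g3 <- as_genome(c(chr1 = "TTCAAGTTGG"))
  ev3 <- make_event("INS1", "chr1", 3L, 3L, inserted_seq = "A")
  hp3 <- detect_homopolymer(g3, ev3)
  expect_true(hp3$flag)
  # oracle: maximal identical run containing the insertion point in the
  # edited sequence TTC[A]AAGTTGG is AAA
  expect_equal(hp3$run, 3L)

  expect_error(detect_homopolymer(g, make_event("SBS", "chr1", 4L, 4L)),
               "context detection")
})

test_that("polynucleotide repeat requires tandem copies at a junction", {
  #               123456789
  g <- as_genome(c(chr1 = "GGCTATAGG"))
  ev <- make_event("DEL_GE2", "chr1", 4L, 5L, deleted_seq = "TA")
  tr <- detect_polynucleotide_repeat(g, ev)
  expect_true(tr$flag)
  expect_identical(tr$unit, "TA")

  # single copy is not a repeat
  g2 <- as_genome(c(chr1 = "AAGCTTAGG"))
  ev2 <- make_event("DEL_GE2", "chr1", 3L, 4L, deleted_seq = "GC")
  expect_false(detect_polynucleotide_repeat(g2, ev2)$flag)

  # homopolymer region: period-1 excluded, homopolymer flag takes over
  g3 <- as_genome(c(chr1 = "GGAAAAGGCC"))
  ev3 <- make_event("DEL_GE2", "chr1", 3L, 4L, deleted_seq = "AA")
  expect_false(detect_polynucleotide_repeat(g3, ev3)$flag)
  expect_true(detect_homopolymer(g3, ev3)$flag)

  # a tandem repeat buried deep inside a large deletion does not flag:
  # embed ACACAC mid-deletion in an otherwise square-free sequence (no
  # tandem of any unit exists anywhere else, verified by oracle below)
  sf <- "1"
  for (i in 1:7)
    sf <- paste(c("1" = "123", "2" = "13",
                  "3" = "2")[strsplit(sf, "")[[1]]], collapse = "")
  sf <- chartr("123", "ACG", substr(sf, 1, 150))
  has_square <- function(s) {
    v <- strsplit(s, "")[[1]]
    for (u in 1:6) for (i in seq_len(length(v) - 2 * u + 1))
      if (identical(v[i:(i + u - 1)], v[(i + u):(i + 2 * u - 1)]))
        return(TRUE)
    FALSE
  }
  expect_false(has_square(sf))   # oracle: flanks are genuinely tandem-free
  seq4 <- paste0(substr(sf, 1, 80), "ACACAC", substr(sf, 81, 150))
  g4 <- as_genome(c(chr1 = seq4))
  core <- substr(seq4, 61, 110)  # deletion spans the buried ACACAC
  ev4 <- make_event("DEL_GE2", "chr1", 61L, 110L, deleted_seq = core)
  expect_false(detect_polynucleotide_repeat(g4, ev4)$flag)
})

test_that("insertions creating a tandem duplication flag as repeat", {
  #               12345678901
  g <- as_genome(c(chr1 = "GGGTAGCCAGG"))
  # inserting TA right after the existing TA makes TATA
  ev <- make_event("INS_GE2", "chr1", 5L, 5L, inserted_seq = "TA")
  tr <- detect_polynucleotide_repeat(g, ev)
  expect_true(tr$flag)
  expect_identical(tr$unit, "TA")
})

test_that("microhomology length equals the junction prefix/suffix match", {
  #               123456789012
  g <- as_genome(c(chr1 = "GGTACGTACTGG"))
  # delete TACG (3..6); downstream flank TACTGG shares prefix TAC
  ev <- make_event("DEL_GE2", "chr1", 3L, 6L, deleted_seq = "TACG")
  mh <- detect_microhomology(g, ev)
  expect_true(mh$flag)
  expect_equal(mh$len, 3L)
  expect_identical(mh$seq, "TAC")
  expect_equal(mh$len, mh_oracle("GG", "TACG", "TACTGG"))

  # junction with no shared sequence
  g2 <- as_genome(c(chr1 = "AAAACCGGTTTT"))
  ev2 <- make_event("DEL_GE2", "chr1", 5L, 8L, deleted_seq = "CCGG")
  mh2 <- detect_microhomology(g2, ev2)
  expect_false(mh2$flag)
  expect_equal(mh2$len, 0L)
  expect_identical(mh2$seq, "")

  expect_error(detect_microhomology(g, make_event("DEL1", "chr1", 3L, 3L,
                                                  deleted_seq = "T")),
               "context detection")
})

test_that("microhomology detector agrees with the brute-force oracle", {
  set.seed(72)
  g <- as_genome(c(chr1 = random_seq(20000)))
  s <- as.character(g[[1]])
  for (i in 1:300) {
    size <- sample(2:30, 1)
    p <- sample(50:(20000 - 50 - size), 1)
    D <- substr(s, p, p + size - 1L)
    ev <- make_event("DEL_GE2", "chr1", p, p + size - 1L, deleted_seq = D)
    mh <- detect_microhomology(g, ev)
    U <- substr(s, p - 10L, p - 1L)
    W <- substr(s, p + size, p + size + 9L)
    expect_equal(mh$len, min(mh_oracle(U, D, W), nchar(D)))
  }
})

test_that("lowering min_len never decreases microhomology flags", {
  set.seed(73)
  g <- as_genome(c(chr1 = random_seq(10000)))
  s <- as.character(g[[1]])
  flags <- sapply(1:4, function(k) {
    set.seed(74)
    mean(replicate(150, {
      size <- sample(2:20, 1)
      p <- sample(30:(10000 - 30 - size), 1)
      ev <- make_event("DEL_GE2", "chr1", p, p + size - 1L,
                       deleted_seq = substr(s, p, p + size - 1L))
      detect_microhomology(g, ev, min_len = k)$flag
    }))
  })
  expect_true(all(diff(flags) <= 0))
  # at min_len = 1 random junctions flag at roughly 1 - (3/4)^2 per pair;
  # well above the min_len = 2 rate
  expect_gt(flags[1], flags[2] + 0.2)
})

test_that("context flags are invariant to the input alignment dialect", {
  #               12345678901234
  g <- as_genome(c(chr1 = "GGCACACATTTGGC"))
  # deletion of one CA unit, expressed left- and right-aligned
  left <- make_calls("s1", "chr1", 2L, "GCA", "G", zygosity = "HET")
  right <- make_calls("s1", "chr1", 6L, "ACA", "A", zygosity = "HET")
  evs <- lapply(list(left, right), function(cl) {
    merge_events(normalize_variants(cl, g), filter_policy())
  })
  expect_identical(evs[[1]]$start, evs[[2]]$start)
  anns <- lapply(evs, annotate_events, genome = g)
  expect_identical(anns[[1]]$tandem_repeat, anns[[2]]$tandem_repeat)
  expect_identical(anns[[1]]$homopolymer, anns[[2]]$homopolymer)
  expect_identical(anns[[1]]$microhomology, anns[[2]]$microhomology)
  expect_true(anns[[1]]$tandem_repeat)
})

test_that("single-base indels classify into A/T vs G/C sites", {
  expect_identical(classify_site_base(make_event("DEL1", "chr1", 5L, 5L,
                                                 deleted_seq = "T")), "AT")
  expect_identical(classify_site_base(make_event("INS1", "chr1", 5L, 5L,
                                                 inserted_seq = "G")), "GC")
  expect_true(is.na(classify_site_base(make_event("DEL_GE2", "chr1", 5L, 6L,
                                                  deleted_seq = "AT"))))
})

test_that("context summary reports non-exclusive counts and percentages", {
  events <- rbind(make_event("DEL_GE2", "chr1", 10L, 12L,
                             deleted_seq = "AAA", sample_id = "s1"),
                  make_event("DEL_GE2", "chr1", 50L, 52L,
                             deleted_seq = "TAG", sample_id = "s1"),
                  make_event("DEL1", "chr1", 90L, 90L,
                             deleted_seq = "T", sample_id = "s1"))
  ann <- data.frame(event_id = events$event_id,
                    category = events$category,
                    homopolymer = c(TRUE, FALSE, TRUE),
                    tandem_repeat = c(TRUE, FALSE, FALSE),
                    microhomology = c(FALSE, FALSE, NA),
                    site_base_class = c(NA, NA, "AT"),
                    stringsAsFactors = FALSE)
  sm <- summarize_context(events, ann)
  del2 <- sm[sm$category == "DEL_GE2" & sm$bin == "all", ]
  expect_equal(del2$n, 2L)
  # the double-flagged event counts once in each column
  expect_equal(del2$n_homopolymer, 1L)
  expect_equal(del2$n_repeat_or_mh, 1L)
  expect_equal(del2$pct_homopolymer, 50)
  del1 <- sm[sm$category == "DEL1", ]
  expect_equal(del1$pct_at_site, 100)
  # all-unflagged input gives zero proportions
  ann0 <- ann
  ann0$homopolymer <- FALSE
  ann0$tandem_repeat <- FALSE
  ann0$microhomology <- FALSE
  sm0 <- summarize_context(events, ann0)
  expect_true(all(sm0$pct_homopolymer == 0))
  expect_true(all(sm0$pct_repeat_or_mh == 0))
})
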