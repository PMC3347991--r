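test_that("make_hairpin constructions hit the intended criteria outcomes", {
  mat <- "UUUGGUUUGAAGGGAGCUCUA"
  hp0 <- make_hairpin(mat, 0)
  st0 <- fold_mfe(hp0$sequence)
  d0 <- locate_duplex(list(sequence = hp0$sequence, mature_offset = 0L),
                      st0, nchar(mat))
  expect_true(d0$ok)
  expect_equal(d0$duplex_mismatches, 0L)

  ev6 <- local({
    hp <- make_hairpin(mat, 6)
    evaluate_candidate(list(sequence = hp$sequence, mature_offset = 0L),
                       fold_mfe(hp$sequence), nchar(mat))
  })
  expect_false(ev6$pass_flags[["duplex"]])

  # GC-rich construct fails the A+U band
  gc_mat <- "GCGGCCGCGGCCGCGGCCGC"
  hp_gc <- make_hairpin(gc_mat, 0, loop_len = 4)
  ev_gc <- evaluate_candidate(list(sequence = hp_gc$sequence,
                                   mature_offset = 0L),
                              fold_mfe(hp_gc$sequence), nchar(gc_mat))
  expect_lt(ev_gc$au_pct, 30)
  expect_false(ev_gc$pass_flags[["au"]])

  expect_error(make_hairpin("ACGUACGU", 0), "18-24")
  expect_error(make_hairpin(mat, 15), "too large")
})

test_that("make_transcriptome plants are retrievable and deterministic", {
  spec <- default_sim_spec(seed = 77)
  sim <- make_transcriptome(spec)
  expect_equal(nrow(sim$truth), 40L)
  expect_equal(sum(sim$truth$kind == "planted"), 20L)
  expect_true(any(sim$truth$strand == "-"))
  # each planted mature is retrievable at its recorded coordinates
  for (i in which(sim$truth$kind == "planted")) {
    t <- sim$truth[i, ]
    seq <- sim$transcripts$sequence[sim$transcripts$id == t$transcript_id]
    sub <- substring(seq, t$mat_start + 1, t$mat_end)
    want <- spec$planted$mature[spec$planted$mirna_id == t$mirna_id]
    if (t$strand == "-") sub <- revcomp_rna(sub)
    expect_equal(sub, want, info = t$mirna_id)
  }
  # decoys carry the intact mature too (homology preserved)
  for (i in which(sim$truth$kind == "decoy")) {
    t <- sim$truth[i, ]
    seq <- sim$transcripts$sequence[sim$transcripts$id == t$transcript_id]
    want <- spec$decoys$mature[spec$decoys$mirna_id == t$mirna_id]
    expect_equal(substring(seq, t$mat_start + 1, t$mat_end), want)
  }
  # byte-identical under the same seed
  sim2 <- make_transcriptome(default_sim_spec(seed = 77))
  expect_identical(sim$transcripts$sequence, sim2$transcripts$sequence)
  sim3 <- make_transcriptome(default_sim_spec(seed = 78))
  expect_false(identical(sim$transcripts$sequence,
                         sim3$transcripts$sequence))
  # alphabet invariant
  expect_true(all(grepl("^[ACGU]+$", sim$transcripts$sequence)))
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(702)
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:5) {
    s <- random_rna(60)
    sh <- pinemir:::.dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucs(sh), dinucs(s))
  }
})

test_that("engineered target sites score exactly as intended", {
  mat <- "UGAUUGAGCCGUGCCAAUAUC"
  specs <- data.frame(mirna_id = "m", mature = mat,
                      score = c(0, 0.5, 1, 2, 3), stringsAsFactors = FALSE)
  tt <- make_target_transcripts(specs, seed = 3)
  for (i in seq_len(nrow(tt$truth))) {
    t <- tt$truth[i, ]
    site <- substring(
      tt$transcripts$sequence[tt$transcripts$id == t$transcript_id],
      t$site_start + 1, t$site_end)
    expect_equal(score_duplex(mat, site)$score, t$score)
  }
  expect_error(make_target_transcripts(
    data.frame(mirna_id = "m", mature = mat, score = 0.25), seed = 1),
    "unreachable")
  tt2 <- make_target_transcripts(specs, seed = 3)
  expect_identical(tt$transcripts$sequence, tt2$transcripts$sequence)
})

test_that("make_ct_table is deterministic and respects its spec", {
  spec <- data.frame(gene = c("a", "b"), fold = c(2, 8), sd = 0.1,
                     replicates = 3, stringsAsFactors = FALSE)
  t1 <- make_ct_table(spec, seed = 9)
  t2 <- make_ct_table(spec, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$ct > 0))
  expect_equal(sum(t1$gene == "a"), 6L)   # 3 replicates x 2 samples
})
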