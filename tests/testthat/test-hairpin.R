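test_that("AMFE/MFEI formulas and guard rails", {
  r <- compute_mfei(-50, 100, 50)
  expect_equal(r$amfe, 50)
  expect_equal(r$mfei, 1.00)
  r2 <- compute_mfei(-15, 100, 70)
  expect_equal(r2$amfe, 15)
  expect_equal(r2$mfei, 0.50)
  expect_error(compute_mfei(-10, 100, 100), "undefined MFEI")

  # formula oracle on random triples
  set.seed(401)
  for (i in 1:25) {
    mfe <- -runif(1, 1, 120)
    len <- sample(60:500, 1)
    au <- runif(1, 5, 95)
    r <- compute_mfei(mfe, len, au)
    expect_equal(r$amfe, abs(mfe) * 100 / len)
    expect_equal(r$mfei, (abs(mfe) * 100 / len) / (100 - au))
  }
})

test_that("locate_duplex: perfect duplex, arms, star and overhang", {
  mat <- "UGAUUGAGCCGUGCCAAUAUC"
  hp <- make_hairpin(mat, 0)
  st <- fold_mfe(hp$sequence)
  d <- locate_duplex(list(sequence = hp$sequence, mature_offset = 0L),
                     st, nchar(mat))
  expect_true(d$ok)
  expect_equal(d$arm, "5p")
  expect_equal(d$duplex_mismatches, 0L)
  # star is the reverse complement (overhang clipped at the sequence end)
  expect_equal(substring(d$star, 1, nchar(mat)), revcomp_rna(mat))

  # same hairpin, mature taken as the 3' arm (the star side)
  off3 <- nchar(hp$sequence) - nchar(mat)
  d3 <- locate_duplex(list(sequence = hp$sequence,
                           mature_offset = off3), st, nchar(mat))
  expect_true(d3$ok)
  expect_equal(d3$arm, "3p")
})

test_that("locate_duplex rejects loop-straddling and open chains", {
  # hand-built: 10-bp stem, 4-nt loop; "mature" of 8 nt straddling the loop
  seq <- "GGGGGGGGGGAAAACCCCCCCCCC"
  db <-  "((((((((((....))))))))))"
  st <- structure(list(dotbracket = db, mfe = -10,
                       pairs = .pairs_from_db_test(db), sequence = seq),
                  class = "rna_structure")
  d <- locate_duplex(list(sequence = seq, mature_offset = 7L), st, 8L)
  expect_false(d$ok)
  expect_match(d$reason, "loop")

  open <- structure(list(dotbracket = strrep(".", 24), mfe = 0,
                         pairs = rep(-1L, 24), sequence = seq),
                    class = "rna_structure")
  d2 <- locate_duplex(list(sequence = seq, mature_offset = 0L), open, 8L)
  expect_false(d2$ok)
  expect_equal(d2$reason, "no-stem")
})

test_that("a hand-built 1x1 internal loop opposite the mature counts 2", {
  # stem: mature 1..12 paired except position 6; star bulges one nt
  seq <- paste0("GGAGGCGGAGGC", "AAAA", "GCCUCCACCUCC")
  db <-  paste0("(((((.((((((", "....", ")))))).)))))")
  st <- structure(list(dotbracket = db, mfe = -12,
                       pairs = .pairs_from_db_test(db), sequence = seq),
                  class = "rna_structure")
  d <- locate_duplex(list(sequence = seq, mature_offset = 0L), st, 12L)
  expect_true(d$ok)
  expect_equal(d$duplex_mismatches, 2L)
})

test_that("criteria boundaries read exactly as stated", {
  mat <- "UGAUUGAGCCGUGCCAAUAUC"
  hp <- make_hairpin(mat, 0)
  st <- fold_mfe(hp$sequence)
  win <- list(sequence = hp$sequence, mature_offset = 0L)
  k <- nchar(mat)

  tweak <- function(mfe) {
    s2 <- st; s2$mfe <- mfe
    evaluate_candidate(win, s2, k)
  }
  # MFE inclusive at -15
  expect_true(tweak(-15)$pass_flags[["mfe"]])
  ev <- tweak(-14.9)
  expect_false(ev$pass_flags[["mfe"]])
  expect_true("mfe" %in% ev$reasons)

  # MFEI strict at 0.5: pick mfe so that mfei == 0.5 exactly
  au <- au_content(hp$sequence)
  mfe_edge <- -0.5 * (100 - au) * nchar(hp$sequence) / 100
  ev2 <- tweak(mfe_edge)
  expect_equal(ev2$mfei, 0.5)
  expect_false(ev2$pass_flags[["mfei"]])

  # A+U inclusive at 30 and 70 (synthetic au values through compute flags)
  cfg <- criteria_config()
  for (au_edge in c(30, 70)) {
    flag <- au_edge >= cfg$au_min_pct && au_edge <= cfg$au_max_pct
    expect_true(flag)
  }

  # duplex strict below 6
  cfg6 <- criteria_config(max_duplex_mismatch = 6)
  hp6 <- make_hairpin(mat, 6)
  st6 <- fold_mfe(hp6$sequence)
  ev6 <- evaluate_candidate(list(sequence = hp6$sequence,
                                 mature_offset = 0L), st6, k, cfg6)
  expect_false(ev6$pass_flags[["duplex"]])
  hp5 <- make_hairpin(mat, 5)
  st5 <- fold_mfe(hp5$sequence)
  ev5 <- evaluate_candidate(list(sequence = hp5$sequence,
                                 mature_offset = 0L), st5, k, cfg6)
  expect_true(ev5$pass_flags[["duplex"]])
})

test_that("evaluate is monotone in each threshold", {
  set.seed(402)
  mats <- fixture_reference()$mature[c(1, 5, 9, 23)]
  for (mat in mats) {
    hp <- make_hairpin(mat, sample(0:4, 1))
    st <- fold_mfe(hp$sequence)
    win <- list(sequence = hp$sequence, mature_offset = 0L)
    base <- evaluate_candidate(win, st, nchar(mat))
    loosen <- list(
      criteria_config(mfe_max = 0),
      criteria_config(mfei_min = 0),
      criteria_config(au_min_pct = 1, au_max_pct = 99),
      criteria_config(max_duplex_mismatch = 50))
    for (cfg in loosen) {
      ev <- evaluate_candidate(win, st, nchar(mat), cfg)
      if (base$pass) expect_true(ev$pass)
    }
  }
})

test_that("make_hairpin duplex mismatches are recovered exactly", {
  mats <- fixture_reference()
  mats <- mats$mature[!duplicated(mats$mature)][c(1, 4, 8, 13, 19, 27)]
  for (mat in mats) for (m in 0:5) {
    hp <- make_hairpin(mat, m)
    st <- fold_mfe(hp$sequence)
    d <- locate_duplex(list(sequence = hp$sequence, mature_offset = 0L),
                       st, hp$mature_len)
    expect_true(d$ok, info = paste(mat, m))
    expect_equal(d$duplex_mismatches, m, info = paste(mat, m))
  }
})

test_that("select_best prefers MFEI then shorter window then position", {
  mk <- function(mfei, len, start, pass = TRUE) {
    structure(list(mfei = mfei, pass = pass,
                   window = list(sequence = strrep("A", len),
                                 win_start = start)),
              class = "precursor_candidate")
  }
  expect_null(select_best(list()))
  expect_null(select_best(list(mk(1, 100, 0, pass = FALSE))))
  one <- mk(0.9, 100, 5)
  expect_identical(select_best(list(one)), one)
  best <- select_best(list(mk(0.9, 100, 0), mk(1.1, 100, 0)))
  expect_equal(best$mfei, 1.1)
  best2 <- select_best(list(mk(1.0, 120, 0), mk(1.0, 90, 10)))
  expect_equal(nchar(best2$window$sequence), 90)
  best3 <- select_best(list(mk(1.0, 90, 30), mk(1.0, 90, 10)))
  expect_equal(best3$window$win_start, 10)
})
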