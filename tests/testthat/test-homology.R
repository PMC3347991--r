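ref1 <- data.frame(id = "pde-miR171a", family = "MIR171",
                   mature = "UGAUUGAGCCGUGCCAAUAUC", species_tag = "pde",
                   stringsAsFactors = FALSE)

test_that("planted matures are found with exact coordinates and strand", {
  set.seed(101)
  k <- nchar(ref1$mature)
  bg <- random_rna(200)
  planted <- paste0(substr(bg, 1, 80), ref1$mature, substr(bg, 81, 200))
  tr <- list(id = "tx", sequence = planted)
  hits <- find_hits(tr, ref1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 80L)
  expect_equal(hits$end, 80L + k)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  # three substitutions exceed the mismatch bound
  mut <- ref1$mature
  substr(mut, 3, 3) <- "C"; substr(mut, 9, 9) <- "A"
  substr(mut, 15, 15) <- "G"
  tr3 <- list(id = "tx3",
              sequence = paste0(substr(bg, 1, 80), mut, substr(bg, 81, 200)))
  expect_equal(nrow(find_hits(tr3, ref1)), 0L)

  # reverse-complement planting reports strand "-" in + coordinates
  trm <- list(id = "txm", sequence = paste0(substr(bg, 1, 60),
                                            revcomp_rna(ref1$mature),
                                            substr(bg, 61, 200)))
  hm <- find_hits(trm, ref1)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$strand, "-")
  expect_equal(hm$start, 60L)
  expect_equal(substring(trm$sequence, hm$start + 1, hm$end),
               revcomp_rna(ref1$mature))
})

test_that("find_hits equals the naive Hamming scan (brute-force oracle)", {
  set.seed(102)
  ref <- fixture_reference()[c(1, 6, 9, 20, 34), ]
  for (rep in 1:4) {
    n <- sample(300:1000, 1)
    s <- random_rna(n)
    # plant a couple of (possibly mutated) copies
    ins <- sample(nrow(ref), 2)
    p1 <- sample(0:(n - 60), 1)
    m1 <- ref$mature[ins[1]]
    substr(m1, 5, 5) <- "A"
    s <- paste0(substr(s, 1, p1), m1,
                substr(s, p1 + nchar(m1) + 1, n))
    got <- find_hits(list(id = "t", sequence = s), ref)
    want <- naive_hits(s, "t", ref)
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
})

test_that("raising max_mismatch never removes hits (monotone)", {
  set.seed(103)
  ref <- fixture_reference()[1:4, ]
  s <- paste0(random_rna(150), ref$mature[2], random_rna(150))
  prev <- 0L
  for (mm in 0:3) {
    h <- find_hits(list(id = "t", sequence = s), ref, max_mismatch = mm)
    expect_gte(nrow(h), prev)
    prev <- nrow(h)
    expect_true(all(h$mismatches <= mm))
  }
})

test_that("hit set is symmetric under reverse-complementing the transcript", {
  set.seed(104)
  s <- paste0(random_rna(90), ref1$mature, random_rna(90))
  n <- nchar(s)
  a <- find_hits(list(id = "t", sequence = s), ref1)
  b <- find_hits(list(id = "t", sequence = revcomp_rna(s)), ref1)
  expect_equal(nrow(a), nrow(b))
  # reflection: start' = n - end, strand flipped
  key_a <- sort(paste(n - a$end, ifelse(a$strand == "+", "-", "+")))
  key_b <- sort(paste(b$start, b$strand))
  expect_equal(key_a, key_b)
})

test_that("filter_hits keeps on E-value OR score, strict boundaries", {
  h <- data.frame(mirna_id = "m", transcript_id = "t", start = 0L,
                  end = 21L, strand = "+", mismatches = 0L,
                  score = c(20, 33, 32), e_value = c(1e-5, 0.5, 0.5))
  kept <- filter_hits(h, e_cut = 1e-2, score_cut = 32)
  expect_equal(nrow(kept), 2L)        # e-value pass, score pass; 32 dropped
  expect_false(32 %in% kept$score[kept$e_value >= 1e-2])
})

test_that("degenerate inputs are handled", {
  expect_error(find_hits(list(id = "t", sequence = "ACGUACGUACGU"),
                         ref1[0, ]), "empty reference")
  short <- list(id = "t", sequence = "ACGU")
  expect_equal(nrow(find_hits(short, ref1)), 0L)
})
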