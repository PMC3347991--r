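mat <- "UGAUUGAGCCGUGCCAAUAUC"   # 21 nt, G at several non-seed positions
k <- nchar(mat)

# site with a wobble opposite miRNA position p (needs G or U there)
wobble_site <- function(mature, p) {
  s <- strsplit(revcomp_rna(mature), "")[[1]]
  m <- strsplit(mature, "")[[1]]
  stopifnot(m[p] %in% c("G", "U"))
  s[nchar(mature) - p + 1] <- if (m[p] == "G") "U" else "G"
  paste(s, collapse = "")
}

mismatch_site <- function(mature, p) {
  s <- strsplit(revcomp_rna(mature), "")[[1]]
  m <- strsplit(mature, "")[[1]]
  s[nchar(mature) - p + 1] <- c(A = "A", C = "C", G = "A", U = "C")[[m[p]]]
  paste(s, collapse = "")
}

test_that("score_duplex: identity, wobbles, seed doubling, additivity", {
  expect_equal(score_duplex(mat, revcomp_rna(mat))$score, 0)
  # G:U wobble outside the seed scores 0.5; in the seed it doubles to 1.0
  expect_equal(score_duplex(mat, wobble_site(mat, 11))$score, 0.5)
  expect_equal(score_duplex(mat, wobble_site(mat, 2))$score, 1.0)
  # one mismatch at position 12 plus one non-seed gap totals 3.0
  s12 <- strsplit(mismatch_site(mat, 12), "")[[1]]
  gap_site <- paste(append(s12, "A", after = 2), collapse = "")  # +1 nt
  r <- score_duplex(mat, gap_site)
  expect_equal(r$score, 3.0)
  expect_equal(r$gap_type, "target_bulge")
  # length difference beyond max_gaps errors
  expect_error(score_duplex(mat, substring(revcomp_rna(mat), 1, k - 2)),
               "max_gaps")
})

test_that("identity holds for random matures", {
  set.seed(501)
  for (i in 1:10) {
    m <- random_rna(sample(19:23, 1))
    expect_equal(score_duplex(m, revcomp_rna(m))$score, 0, info = m)
  }
})

test_that("scan_targets finds planted sites and honors the cut-off", {
  set.seed(502)
  tt <- make_target_transcripts(
    data.frame(mirna_id = "m", mature = mat,
               score = c(0, 0.5, 1, 2, 3, 3.5), stringsAsFactors = FALSE),
    seed = 99)
  hits <- scan_targets(list(id = "m", mature = mat), tt$transcripts)
  got <- setNames(rep(NA_real_, 6), tt$truth$transcript_id)
  for (i in seq_len(nrow(hits)))
    got[hits$transcript_id[i]] <- hits$score[i]
  expect_equal(unname(got[1:5]), c(0, 0.5, 1, 2, 3))
  expect_true(is.na(got[6]))   # the 3.5 site is excluded at <= 3
  # reported coordinates match the truth table
  m5 <- merge(hits, tt$truth, by = "transcript_id")
  expect_true(all(m5$site_start.x == m5$site_start.y))
})

test_that("scan_targets agrees with naive all-window rescoring", {
  set.seed(503)
  tr <- make_target_transcripts(
    data.frame(mirna_id = "m", mature = mat, score = c(1, 2.5),
               stringsAsFactors = FALSE), seed = 17,
    transcript_len = 800)$transcripts
  cut <- 3
  hits <- scan_targets(list(id = "m", mature = mat), tr, score_cut = cut)
  for (ti in seq_len(nrow(tr))) {
    s <- tr$sequence[ti]; n <- nchar(s)
    brute <- list()
    for (L in (k - 1):(k + 1)) {
      for (st in 0:(n - L)) {
        sc <- score_duplex(mat, substring(s, st + 1, st + L))$score
        if (sc <= cut)
          brute[[length(brute) + 1L]] <- data.frame(start = st,
                                                    end = st + L,
                                                    score = sc)
      }
    }
    brute <- do.call(rbind, brute)
    mine <- hits[hits$transcript_id == tr$id[ti], ]
    # every reported site exists in the brute set at the same score
    for (i in seq_len(nrow(mine))) {
      hit <- brute[brute$start == mine$site_start[i] &
                   brute$end == mine$site_end[i], ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$score, mine$score[i])
    }
    # every brute window overlaps a reported site with score <= its own
    for (i in seq_len(nrow(brute))) {
      ov <- mine[mine$site_start < brute$end[i] &
                 mine$site_end > brute$start[i], ]
      expect_gte(nrow(ov), 1L)
      expect_lte(min(ov$score), brute$score[i])
    }
  }
})

test_that("lowering the score cut never adds sites", {
  set.seed(504)
  tr <- make_target_transcripts(
    data.frame(mirna_id = "m", mature = mat, score = c(0, 2, 3),
               stringsAsFactors = FALSE), seed = 23)$transcripts
  h3 <- scan_targets(list(id = "m", mature = mat), tr, score_cut = 3)
  h1 <- scan_targets(list(id = "m", mature = mat), tr, score_cut = 1)
  expect_true(all(paste(h1$transcript_id, h1$site_start) %in%
                  paste(h3$transcript_id, h3$site_start)))
  expect_lte(nrow(h1), nrow(h3))
})

test_that("cleavage maps to the bond opposite miRNA positions 10/11", {
  for (offset in c(100, 105)) {
    tr <- as_transcripts("t", paste0(strrep("A", offset), revcomp_rna(mat),
                                     strrep("A", 80)))
    h <- scan_targets(list(id = "m", mature = mat), tr)
    h <- h[h$score == 0, ]
    expect_equal(h$cleavage_pos, offset + k - 11)   # translation-equivariant
    expect_true(h$cleavage_pos > h$site_start &
                h$cleavage_pos < h$site_end)
  }
  # a bulge between positions 10 and 11 flags the site
  fake <- data.frame(site_end = 121L, gap_type = "target_bulge",
                     gap_pos = 10L, stringsAsFactors = FALSE)
  expect_false(predict_cleavage(fake, mat)$ok)
})

test_that("alignment rendering round-trips through the penalty table", {
  tr <- as_transcripts("t", paste0(strrep("C", 30), revcomp_rna(mat),
                                   strrep("C", 30)))
  h <- scan_targets(list(id = "m", mature = mat), tr)
  h <- h[h$score == 0, ][1, ]
  al <- render_alignment(h, mat)
  lines <- strsplit(al, "\n")[[1]]
  expect_length(lines, 3)
  mid <- sub("^   ", "", lines[2])
  expect_equal(mid, strrep("|", k))          # perfect duplex: all dashes
  expect_equal(score_from_alignment(al, k), 0)

  # one wobble renders exactly one "o" and re-scores to 0.5
  site <- wobble_site(mat, 11)
  h2 <- h
  h2$site <- site; h2$gap_type <- "none"; h2$gap_pos <- NA_integer_
  al2 <- render_alignment(h2, mat)
  mid2 <- sub("^   ", "", strsplit(al2, "\n")[[1]][2])
  expect_equal(sum(strsplit(mid2, "")[[1]] == "o"), 1)
  expect_equal(score_from_alignment(al2, k),
               score_duplex(mat, site)$score)
})
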