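# profiles constructed directly at known per-motif bp; total = capped sum
pp <- function(id, len, ...) {
  bp <- c(...)
  pentaplex:::profile_from_bp(id, len, bp, total_repeat_bp = min(len, sum(bp)))
}
targets <- c("TTTTA", "TTTCA")

test_that("classify_pair applies the stated defaults", {
  # p1 pure TTTTA 150 bp; p2 mixed 60+90: qualifies
  c1 <- classify_pair(pp("p", 151, TTTTA = 150, TTTCA = 0),
                      pp("p", 151, TTTTA = 60, TTTCA = 90), targets)
  expect_true(c1$qualifies)
  expect_identical(c1$reason, "ok")
  expect_equal(unname(c1$per_motif_pair_bp[canonical_key("TTTTA")]), 210)
  expect_equal(unname(c1$per_motif_pair_bp[canonical_key("TTTCA")]), 90)

  # both pure in one motif: the aggregate misses the second motif entirely
  c2 <- classify_pair(pp("p", 151, TTTTA = 150, TTTCA = 0),
                      pp("p", 151, TTTTA = 150, TTTCA = 0), targets)
  expect_false(c2$qualifies)
  expect_identical(c2$reason, "motif_below_min")

  # one read at 120 bp: read criterion is strict >125
  c3 <- classify_pair(pp("p", 151, TTTTA = 0, TTTCA = 120),
                      pp("p", 151, TTTTA = 150, TTTCA = 0), targets)
  expect_false(c3$qualifies)
  expect_identical(c3$reason, "read_below_min")

  expect_error(
    classify_pair(pp("p", 151, TTTTA = 150), pp("p", 151, TTTTA = 150),
                  targets),
    "target motif set")
})

test_that("classification boundaries: >125 bp per read, >=50 bp per motif", {
  # exactly 125 bp total repeat fails (strict); 126 passes
  at125 <- pp("p", 151, TTTTA = 75, TTTCA = 50)
  at126 <- pp("p", 151, TTTTA = 76, TTTCA = 50)
  big <- pp("p", 151, TTTTA = 100, TTTCA = 51)
  expect_false(classify_pair(at125, big, targets)$qualifies)
  expect_true(classify_pair(at126, big, targets)$qualifies)
  # exactly 50 bp of a motif across the pair passes (>=); 49 fails
  a <- pp("p", 151, TTTTA = 101, TTTCA = 25)
  b25 <- pp("p", 151, TTTTA = 101, TTTCA = 25)
  b24 <- pp("p", 151, TTTTA = 102, TTTCA = 24)
  expect_true(classify_pair(a, b25, targets)$qualifies)
  expect_false(classify_pair(a, b24, targets)$qualifies)
})

test_that("classify_pair is symmetric and threshold-monotone (property)", {
  set.seed(31)
  for (i in 1:200) {
    bp1 <- sample(c(0, 24:26, 49:51, 60:155), 2)
    bp2 <- sample(c(0, 24:26, 49:51, 60:155), 2)
    p1 <- pp("p", 151, TTTTA = bp1[1], TTTCA = bp1[2])
    p2 <- pp("p", 151, TTTTA = bp2[1], TTTCA = bp2[2])
    q12 <- classify_pair(p1, p2, targets)
    q21 <- classify_pair(p2, p1, targets)
    expect_identical(q12$qualifies, q21$qualifies)
    # hand-applied thresholds
    want <- p1$total_repeat_bp > 125 && p2$total_repeat_bp > 125 &&
      bp1[1] + bp2[1] >= 50 && bp1[2] + bp2[2] >= 50
    expect_identical(q12$qualifies, want)
    # raising either threshold never makes a non-qualifier qualify
    stricter <- classify_pair(p1, p2, targets, min_read_bp = 140,
                              min_motif_bp = 70)
    expect_false(stricter$qualifies && !q12$qualifies)
  }
})

test_that("screen_sample counts qualifying pairs and applies min_pairs", {
  good1 <- strrep("TTTTA", 30)                            # 150 bp pure
  good2 <- paste0(strrep("TTTTA", 12), strrep("TTTCA", 18))
  bad <- random_read(151)
  mkpairs <- function(ngood, nbad) {
    data.frame(pair_id = sprintf("p%02d", seq_len(ngood + nbad)),
               read1 = c(rep(good1, ngood), rep(bad, nbad)),
               read2 = c(rep(good2, ngood), rep(bad, nbad)))
  }
  set.seed(8)
  expect_false(screen_sample(mkpairs(2, 3), targets)$flagged)
  r3 <- screen_sample(mkpairs(3, 2), targets)
  expect_true(r3$flagged)
  expect_equal(r3$qualifying_pairs, 3)

  # order independence
  perm <- mkpairs(3, 4)
  shuffled <- perm[sample(nrow(perm)), ]
  expect_equal(screen_sample(shuffled, targets)$qualifying_pairs, 3)

  # empty stream
  e <- screen_sample(NULL, targets)
  expect_equal(e$qualifying_pairs, 0)
  expect_false(e$flagged)
})

test_that("the purity criterion is OR-ed in when requested", {
  # both reads ~99% TTGTA but only a single motif: fails the mixed-motif bp
  # rule, qualifies via the >90% fraction route
  pure <- paste0(strrep("TTGTA", 30), "C")
  pairs <- data.frame(pair_id = "p1", read1 = pure, read2 = pure)
  off <- screen_sample(pairs, "TTGTA", min_motif_bp = 500)
  expect_equal(off$qualifying_pairs, 0)
  on <- screen_sample(pairs, "TTGTA", min_motif_bp = 500, min_fraction = 0.9)
  expect_equal(on$qualifying_pairs, 1)
  expect_identical(on$pairs$qualified_by, "fraction")
})

test_that("screen_cohort returns one ordered row per sample", {
  good <- data.frame(read1 = rep(strrep("TTTTA", 30), 3),
                     read2 = rep(paste0(strrep("TTTTA", 13),
                                        strrep("TTTCA", 17)), 3))
  set.seed(3)
  wt <- data.frame(read1 = replicate(2, random_read(151)),
                   read2 = replicate(2, random_read(151)))
  res <- suppressMessages(
    screen_cohort(list(s2 = wt, s1 = good, s3 = wt), targets))
  expect_identical(res$sample_id, c("s1", "s2", "s3"))
  expect_identical(res$flagged, c(TRUE, FALSE, FALSE))

  expect_error(suppressMessages(
    screen_cohort(list(a = good, a = wt), targets)), "duplicate")
  expect_error(screen_cohort(list(), targets), ">= 1 sample")
  one <- suppressMessages(screen_cohort(list(only = good), targets))
  expect_equal(nrow(one), 1)
})
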