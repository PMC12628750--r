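fame_set <- c("TTTTA", "TTTCA", "TTGTA")

test_that("extract_region_reads selects by overlap and orients reads", {
  tab <- data.frame(
    read_id = c("in", "left", "rev"),
    contig = "chr5",
    start = c(10356300, 10356000, 10356350),
    end = c(10356500, 10356338, 10356700),
    strand = c("forward", "forward", "reverse"),
    seq = c("ACGTACGT", "ACGTACGT", "AAACCC"))
  out <- suppressMessages(extract_region_reads(tab, "chr5:10356339-10356411"))
  expect_identical(out$read_id, c("in", "rev"))
  # reverse-strand read comes back reverse-complemented
  expect_identical(out$seq[out$read_id == "rev"], "GGGTTT")
  expect_identical(out$seq[out$read_id == "in"], "ACGTACGT")

  expect_warning(empty <- extract_region_reads(tab, "chrX:1-100"), "absent")
  expect_equal(nrow(empty), 0)
})

test_that("count_motifs counts tandem-run copies", {
  # repeat-primed PCR primer: 21 bp anchor + 6 tandem TTGTA copies
  primer <- "TACGCATCCCAGTTTGAGACGTTGTATTGTATTGTATTGTATTGTATTGTA"
  cnt <- count_motifs(primer, "TTGTA")
  expect_equal(cnt$TTGTA_copies, 6)
  expect_equal(cnt$total_repeat_bp, 30)

  # error-free synthesis round trip
  cfg <- parse_config("(TTTTA)100-(TTTCA)100-(TTTTA)100-(TTGTA)100",
                      left_flank = strrep("GAC", 17),
                      right_flank = strrep("CTG", 17))
  cnt2 <- count_motifs(config_to_sequence(cfg), fame_set)
  expect_equal(cnt2$total_repeat_bp, 2000)  # 400 pentamer copies
  # per-motif copies: maximal runs cross block junctions by a few bases, so
  # copies are within one copy above the synthesized counts
  expect_true(abs(cnt2$TTTTA_copies - 200) <= 1.5)
  expect_true(abs(cnt2$TTTCA_copies - 100) <= 1.5)
  expect_true(abs(cnt2$TTGTA_copies - 100) <= 1.5)

  # flank-only read
  cnt3 <- count_motifs(paste0(strrep("GAC", 30), strrep("CTG", 30)), fame_set)
  expect_equal(cnt3$total_repeat_bp, 0)
})

test_that("filter_wildtype partitions exactly at 800 bp", {
  recs <- data.frame(read_id = c("a", "b", "c", "d"),
                     total_repeat_bp = c(40, 900, 4500, 800))
  kept <- suppressMessages(filter_wildtype(recs))
  expect_identical(kept$read_id, c("b", "c", "d"))  # 800 kept: < is strict
  expect_equal(nrow(suppressMessages(
    filter_wildtype(recs[integer(0), , drop = FALSE]))), 0)
})

test_that("detect_miscall_artifact requires reverse strand and majority TTCCA", {
  mk <- function(n_ttcca, n_tttca, n_tttta, strand) {
    data.frame(seq = paste0(strrep("TTCCA", n_ttcca), strrep("TTTCA", n_tttca),
                            strrep("TTTTA", n_tttta)),
               strand = strand)
  }
  expect_true(detect_miscall_artifact(mk(80, 10, 10, "reverse")))
  expect_false(detect_miscall_artifact(mk(80, 10, 10, "forward")))
  expect_false(detect_miscall_artifact(mk(10, 45, 45, "reverse")))
  expect_warning(u <- detect_miscall_artifact(mk(80, 10, 10, "unknown")),
                 "unknown strand")
  expect_false(u)
})

test_that("segment_read round-trips error-free configurations exactly", {
  s <- segment_read(
    config_to_sequence(parse_config("(TTTTA)100-(TTTCA)95-(TTTTA)100-(TTGTA)120")),
    fame_set)
  expect_identical(s$structure_string,
                   "(TTTTA)100-(TTTCA)95-(TTTTA)100-(TTGTA)120")

  # property: random clean multi-block configurations with flanks
  set.seed(61)
  for (i in 1:20) {
    nb <- sample(2:5, 1)
    repeat {
      motifs <- sample(fame_motifs, nb, replace = TRUE)
      keys <- vapply(motifs, canonical_key, character(1))
      if (all(keys[-1] != keys[-nb])) break
    }
    copies <- sample(20:200, nb, replace = TRUE)
    txt <- paste(sprintf("(%s)%d", motifs, copies), collapse = "-")
    seg <- segment_read(config_to_sequence(parse_config(txt)), fame_motifs)
    expect_identical(seg$structure_string, txt, info = txt)

    # with random flanks the synthesized boundary is recovered up to the
    # flank's chance continuation of the repeat period (at most one copy)
    cfg <- parse_config(txt, left_flank = random_read(100),
                        right_flank = random_read(100))
    segf <- segment_read(config_to_sequence(cfg), fame_motifs)
    expect_equal(gsub("[0-9]+", "", segf$structure_string),
                 gsub("[0-9]+", "", txt), info = txt)
    expect_true(all(abs(segf$blocks$copies - copies) <= 1), info = txt)
  }
})

test_that("segmentation depends on the supplied motif set", {
  seq15 <- strrep("TTTTATTTTATTTCA", 50)
  with15 <- segment_read(seq15, c(fame_set, "TTTTATTTTATTTCA"))
  expect_identical(with15$structure_string, "(TTTTATTTTATTTCA)50")
  without <- segment_read(seq15, fame_set)
  # without the composite motif the 15-mer periodicity cannot be named: no
  # composite block, and no (false) pure TTTCA expansion block either
  expect_false(grepl("TTTTATTTTATTTCA", without$structure_string))
  expect_false(grepl("\\(TTTCA\\)[0-9]{2,}", without$structure_string))
})

test_that("small sandwiched tracts are reported as interruptions", {
  s <- segment_read(
    config_to_sequence(parse_config("(TTTTA)50-(TTTCA)2-(TTTTA)50")),
    fame_set)
  expect_identical(s$structure_string, "(TTTTA)102")  # tract spans both sides
  expect_equal(nrow(s$interruptions), 1)
  expect_identical(s$interruptions$motif, "TTTCA")
  expect_equal(s$interruptions$copies, 2)
})

test_that("segment_read tolerates read-scale noise", {
  set.seed(17)
  cfg <- parse_config("(TTTTA)100-(TTTCA)95-(TTTTA)100-(TTGTA)120",
                      left_flank = random_read(200),
                      right_flank = random_read(200))
  clean <- config_to_sequence(cfg)
  noisy <- pentaplex:::.apply_long_errors(clean, 0.02, 0.01, 0.01)$seq
  seg <- segment_read(noisy, fame_motifs)
  expect_identical(gsub("[0-9]+", "", seg$structure_string),
                   "(TTTTA)-(TTTCA)-(TTTTA)-(TTGTA)")
  truth_bp <- cfg$blocks$bp
  expect_true(all(abs(seg$blocks$bp - truth_bp) <= 0.1 * truth_bp))
})

test_that("consensus_structure reports the modal order and dispersion", {
  mkseg <- function(txt, id) {
    segment_read(config_to_sequence(parse_config(txt)), fame_set, read_id = id)
  }
  segs <- c(lapply(1:4, function(i) mkseg("(TTTTA)50-(TTGTA)60", paste0("a", i))),
            list(mkseg("(TTGTA)70", "odd")))
  cons <- consensus_structure(segs)
  expect_identical(cons$structure_string, "(TTTTA)50-(TTGTA)60")
  expect_equal(cons$n_discordant, 1)
  expect_equal(cons$blocks$median_copies, c(50, 60))
  expect_error(consensus_structure(list()), "no segmentations")

  # mosaic block sizes: median and MAD reflect the spread
  set.seed(23)
  sizes <- c(80, 90, 100, 110, 120)
  msegs <- lapply(seq_along(sizes), function(i)
    mkseg(sprintf("(TTTTA)50-(TTGTA)%d", sizes[i]), paste0("m", i)))
  mc <- consensus_structure(msegs)
  expect_equal(mc$blocks$median_copies[2], 100)
  expect_gt(mc$blocks$mad_copies[2], 0)
})

test_that("waterfall orders reads by repeat bp and round-trips TSV", {
  mkseg <- function(txt, id)
    segment_read(config_to_sequence(parse_config(txt)), fame_set, read_id = id)
  segs <- list(mkseg("(TTTTA)100-(TTGTA)80", "mid"),
               mkseg("(TTTTA)180-(TTTCA)720", "big"),
               mkseg("(TTTTA)40", "small"))
  ws <- waterfall(segs)
  expect_identical(ws$rows$read_id, c("big", "mid", "small"))
  expect_identical(ws$rows$total_repeat_bp, c(4500L, 900L, 200L))
  # no loss, no duplication
  expect_setequal(ws$rows$read_id, vapply(segs, `[[`, "", "read_id"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_waterfall_tsv(ws, path, config = list(test = TRUE))
  back <- read_waterfall_tsv(path)
  expect_equal(back$read_id, ws$rows$read_id)
  expect_equal(back$total_repeat_bp, ws$rows$total_repeat_bp)
  expect_equal(back$structure_string, ws$rows$structure_string)

  one <- waterfall(segs[2])
  expect_equal(nrow(one$rows), 1)

  # waterfall plot renders to a file without error
  png <- withr::local_tempfile(fileext = ".png")
  plot_waterfall(ws, png)
  expect_true(file.exists(png))
})
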