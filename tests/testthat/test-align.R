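scheme <- scoring_scheme()

test_that("seed index reports exact k-mer occurrences", {
  s <- cbs_scaffold_set()
  idx_wt <- seed_index(s$wt)
  idx_mu <- seed_index(s$mu)

  kmer <- substr(s$wt$sequence, 2000, 2014)
  expect_true(2000L %in% idx_wt$lookup(kmer))

  ## a k-mer overlapping the engineered marker exists only on MU
  mk <- substr(s$mu$sequence, 3203, 3217)
  expect_length(idx_mu$lookup(mk), 1L)
  expect_length(idx_wt$lookup(mk), 0L)

  ## k-mers inside the duplicated segment (between divergent offsets)
  ## occur at both copies on MU
  dup <- substr(s$mu$sequence, 3280, 3294)  # second copy, offsets 40..54
  expect_gte(length(idx_mu$lookup(dup)), 2L)

  expect_error(seed_index(s$wt, k = 7L), "at least 8")
})

test_that("exact reads place perfectly and ties break to the lowest start", {
  s <- cbs_scaffold_set()
  r <- substr(s$wt$sequence, 2000, 2149)
  a <- align_read(r, s$wt, scheme)
  expect_true(a$mapped)
  expect_equal(a[, c("score", "start", "left_clip", "right_clip")],
               data.frame(score = 150L, start = 2000L, left_clip = 0L,
                          right_clip = 0L))
  expect_identical(a$cigar, "150M")

  ## read matching two identical copies -> deterministic leftmost placement
  rep_ref <- withr::with_seed(1L, {
    block <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    paste0(block, mid, block)
  })
  rd <- substr(rep_ref, 10, 45)
  a2 <- align_read(rd, rep_ref, scheme)
  expect_equal(a2$start, 10L)
  expect_equal(align_read(rd, rep_ref, scheme)$start, 10L)
})

test_that("banded extension equals exhaustive affine-gap DP oracles", {
  ## toy read with an internal deletion: R DP oracle + Biostrings oracle
  toy <- withr::with_seed(11L, {
    ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    list(ref = ref, read = paste0(substr(ref, 11, 25), substr(ref, 31, 45)))
  })
  a <- align_read(toy$read, toy$ref, scoring_scheme(k = 8L))
  expect_equal(a$score, r_local_affine(toy$read, toy$ref))
  expect_equal(a$score, bs_local_score(toy$read, toy$ref))
  expect_match(a$cigar, "D")

  ## random error-free 150-mers from both scaffolds vs both scaffolds:
  ## banded heuristic == full-matrix reference path == external DP
  s <- cbs_scaffold_set()
  withr::with_seed(12L, {
    reads <- c(
      substring(s$wt$sequence, st <- sample(4851, 60), st + 149),
      substring(s$mu$sequence, st <- sample(4919, 60), st + 149))
    for (ref in list(s$wt, s$mu)) {
      h <- align_reads(reads, ref, scheme, expected_indel = 68L)
      expect_equal(h$score, align_full_score(reads, ref, scheme))
      sub <- sample(length(reads), 8)
      o <- vapply(reads[sub], function(r) bs_local_score(r, ref$sequence), 0)
      expect_equal(h$score[sub], unname(as.integer(o)))
    }
  })
})

test_that("junction-spanning reads soft-clip on WT and win on MU", {
  s <- cbs_scaffold_set()
  hap <- apply_insertion(s$wt$sequence, s$insertion)  # natural allele
  r <- substr(hap, 3100, 3249)  # spans the left junction and the marker
  awt <- align_read(r, s$wt, scheme, expected_indel = 68L)
  amu <- align_read(r, s$mu, scheme, sites = c(3210L, 3252L),
                    expected_indel = 68L)
  expect_gt(amu$score, awt$score)
  expect_gt(awt$left_clip + awt$right_clip, 0L)
  expect_identical(amu$base_3210, "G")   # natural base against scaffold C
  ## reported scores are consistent with the reported operations
  expect_equal(score_from_cigar(r, s$wt, awt$start, awt$cigar, scheme),
               awt$score)
  expect_equal(score_from_cigar(r, s$mu, amu$start, amu$cigar, scheme),
               amu$score)
})

test_that("scores are symmetric under reverse complement", {
  s <- cbs_scaffold_set()
  rc_ref <- revcomp(s$mu$sequence)
  withr::with_seed(13L, {
    starts <- sample(4919, 25)
    reads <- substring(s$mu$sequence, starts, starts + 149)
    f <- align_reads(reads, s$mu, scheme, expected_indel = 68L)
    r <- align_reads(revcomp(reads), rc_ref, scheme, expected_indel = 68L)
    expect_equal(f$score, r$score)
  })
})

test_that("short anchors are reported unmapped", {
  s <- cbs_scaffold_set()
  junk <- strrep("A", 14)  # below min_anchor once garbage flanks are clipped
  r <- paste0(substr(s$wt$sequence, 1000, 1017), junk)
  a <- align_read(r, s$wt, scoring_scheme(k = 10L))
  expect_false(a$mapped)
  a2 <- align_read(strrep("ACGT", 40), s$wt, scheme)
  expect_true(is.na(a2$score) || !a2$mapped)
})

test_that("pair placement combines mates and gates on orientation", {
  s <- cbs_scaffold_set()
  wt <- s$wt$sequence

  ## shared-sequence pair: identical scores on both scaffolds (the MU
  ## image is shifted by the insertion length)
  p_shared <- read_pairs("p1", substr(wt, 1000, 1149),
                         revcomp(substr(wt, 1150, 1299)))
  ap <- align_pairs(p_shared, s)
  expect_equal(ap$wt$pair_score, ap$mu$pair_score)
  expect_true(ap$wt$proper && ap$mu$proper)

  ## insertion-spanning pair scores strictly higher on MU
  hap <- apply_insertion(wt, s$insertion)
  p_junc <- read_pairs("p2", substr(hap, 3100, 3249),
                       revcomp(substr(hap, 3251, 3400)))
  apj <- align_pairs(p_junc, s)
  expect_gte(apj$mu$pair_score - apj$wt$pair_score, 1L)

  ## swapped mate orientation fails the proper-pair gate
  p_ff <- read_pairs("p3", substr(wt, 1000, 1149), substr(wt, 1150, 1299))
  apf <- align_pairs(p_ff, s)
  expect_false(apf$wt$proper)

  ## an unalignable mate leaves the pair score undefined on that scaffold
  p_half <- read_pairs("p4", substr(wt, 1000, 1149), strrep("ACGT", 38))
  aph <- align_pairs(p_half, s)
  expect_true(is.na(aph$wt$pair_score))
})

test_that("SAM export is structurally valid and position-accurate", {
  s <- cbs_scaffold_set()
  p <- simulate_pairs(make_haplotypes(s, "COMPLEX_HET"),
                      sim_params(coverage = 8, seed = 4L))
  dir <- withr::local_tempdir()
  paths <- write_sam(p, s, dir)
  expect_identical(basename(paths), c("CBS_WT.sam", "CBS_MU.sam"))
  sam <- readLines(paths[2])
  expect_identical(sam[2], "@SQ\tSN:CBS_MU\tLN:5068")
  body <- read.table(text = sam[-(1:3)], sep = "\t", comment.char = "",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(body), 2L * nrow(p))
  mapped <- body[bitwAnd(body$V2, 4L) == 0L, ]
  expect_true(all(mapped$V4 >= 1L & mapped$V4 <= 5068L))
  expect_true(all(grepl("^([0-9]+[MIDS])+$", mapped$V6)))
  ## CIGARs consume exactly the read length
  consumed <- vapply(mapped$V6, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDS]", cg))[[1]]
    sum(lens[ops %in% c("M", "I", "S")])
  }, 0L)
  expect_true(all(consumed == nchar(mapped$V10)))
})
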