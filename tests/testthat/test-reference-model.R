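test_that("scaffold construction satisfies the tandem-duplication invariants", {
  s <- cbs_scaffold_set()
  wt <- s$wt$sequence; mu <- s$mu$sequence
  expect_equal(nchar(wt), 5000L)
  expect_equal(nchar(mu), 5068L)
  expect_equal(s$sites, list(wt_snv = 3184L, mu_marker = 3210L,
                             mu_cis_snv = 3252L))

  ## direct string-construction oracle for the decomposition
  copy <- strsplit(substr(wt, 3173, 3240), "")[[1]]
  copy[s$insertion$divergent_offsets] <- s$insertion$divergent_bases
  copy[38] <- "C"
  expect_identical(mu, paste0(substr(wt, 1, 3172), paste(copy, collapse = ""),
                              substr(wt, 3173, 5000)))

  ## inserted copy differs from its source at exactly divergent + marker
  ins_seq <- strsplit(substr(mu, 3173, 3240), "")[[1]]
  src_seq <- strsplit(substr(wt, 3173, 3240), "")[[1]]
  expect_equal(which(ins_seq != src_seq),
               sort(c(s$insertion$divergent_offsets, 38L)))

  ## marker semantics
  expect_identical(substr(mu, 3210, 3210), "C")
  expect_identical(s$marker$natural_base, "G")
  expect_identical(substr(wt, 3184, 3184), "A")

  ## genomic anchor
  expect_equal(genomic_position(s$wt, 3184), 44483184L)

  ## rare allele has one extra divergent base
  expect_length(cbs_scaffold_set("rare")$insertion$divergent_offsets, 4L)
})

test_that("length and lifting invariants hold over random insertion specs", {
  withr::with_seed(99L, {
    for (rep in 1:15) {
      n <- sample(150:400, 1)
      ref_seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      len <- sample(10:40, 1)
      src_start <- sample(30:(n - len - 30), 1)
      ins <- insertion_spec(src_start, src_start + len - 1L, src_start)
      mu <- apply_insertion(ref_seq, ins)
      expect_equal(nchar(mu) - nchar(ref_seq), len)
      ## direct string oracle
      expect_identical(mu, paste0(substr(ref_seq, 1, src_start - 1),
                                  substr(ref_seq, src_start,
                                         src_start + len - 1),
                                  substr(ref_seq, src_start, n)))
    }
  })
})

test_that("lift_coordinate is a bijection away from the inserted copy", {
  s <- cbs_scaffold_set()
  expect_equal(lift_coordinate(s, "WT", 3184L), 3252L)
  expect_equal(lift_coordinate(s, "WT", 1L), 1L)
  expect_true(is.na(lift_coordinate(s, "MU", 3200L)))
  expect_equal(lift_coordinate(s, "MU", 3241L), 3173L)
  expect_error(lift_coordinate(s, "WT", 5001L), "outside")
  expect_error(lift_coordinate(s, "MU", 0L), "outside")

  ## round trip WT -> MU -> WT is the identity on every WT position
  pos <- seq(1L, 5000L, by = 7L)
  expect_equal(lift_coordinate(s, "MU", lift_coordinate(s, "WT", pos)), pos)
  ## MU positions inside the copy (3173..3240) are the only NA images
  mu_pos <- 1:5068
  img <- lift_coordinate(s, "MU", mu_pos)
  expect_equal(mu_pos[is.na(img)], 3173:3240)
  expect_false(any(duplicated(img[!is.na(img)])))
})

test_that("insertion-description equivalence matches brute-force application", {
  expect_true(equivalent_insertion_descriptions("AAAA", 2, "A", 4, "A"))
  expect_false(equivalent_insertion_descriptions("AAAA", 2, "C", 3, "C"))
  expect_true(equivalent_insertion_descriptions("ACGT", 2, "GG", 2, "GG"))
  expect_error(equivalent_insertion_descriptions("ACGT", 2, "", 2, "A"),
               "empty")
  expect_error(equivalent_insertion_descriptions("ACGT", 9, "A", 2, "A"),
               "outside")

  ## the 68-mer at the analog breakpoint vs its shifted description:
  ## the natural insertion allele admits a 4-base right shift (the copy
  ## matches its template up to the first divergent offset)
  s <- cbs_scaffold_set()
  allele <- apply_insertion(s$wt$sequence, s$insertion)  # no marker
  ins_a <- substr(allele, 3173, 3240)
  ins_b <- substr(allele, 3177, 3244)
  expect_true(equivalent_insertion_descriptions(s$wt$sequence, 3173, ins_a,
                                                3177, ins_b))
  ## a different 68-mer at the shifted position is not equivalent
  ins_c <- paste0("A", substr(ins_b, 2, 68))
  if (ins_c != ins_b)
    expect_false(equivalent_insertion_descriptions(s$wt$sequence, 3173, ins_a,
                                                   3177, ins_c))

  ## randomized agreement with direct string application
  withr::with_seed(7L, {
    ref <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    apply_desc <- function(p, ins)
      paste0(substr(ref, 1, p - 1), ins, substr(ref, p, 30))
    for (i in 1:50) {
      pa <- sample(31, 1); pb <- sample(31, 1)
      ia <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
      ib <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
      expect_equal(equivalent_insertion_descriptions(ref, pa, ia, pb, ib),
                   identical(apply_desc(pa, ia), apply_desc(pb, ib)))
    }
  })
})

test_that("degenerate and invalid specifications are rejected", {
  s <- cbs_scaffold_set()
  ref <- s$wt
  ins <- s$insertion
  expect_error(build_scaffolds(ref, ins, marker_spec(69L, "C"),
                               s$snv), "outside")
  expect_error(build_scaffolds(ref, ins, marker_spec(38L, "G"), s$snv),
               "no expected mismatch")
  expect_error(marker_spec(38L, "C", natural_base = "C"), "differ")
  div_clash <- insertion_spec(3173L, 3240L, 3173L, 38L, "A")
  expect_error(build_scaffolds(ref, div_clash, marker_spec(38L, "C"), s$snv),
               "collides")
  expect_error(reference_region("x", "ACGTN"), "A/C/G/T")
  expect_error(reference_region("x", ""), "non-empty")
  expect_error(build_scaffolds(ref, ins, marker_spec(38L, "C"),
                               snv_spec(3184L, "C", "G")), "does not match")
  ## insertion far from its source is not a tandem arrangement
  far <- insertion_spec(3173L, 3240L, 1000L)
  expect_error(build_scaffolds(ref, far, marker_spec(38L, "C"), s$snv),
               "tandem")
})

test_that("a copy without divergent bases or marker is a perfect tandem", {
  s <- cbs_scaffold_set()
  ins <- insertion_spec(3173L, 3240L, 3173L)
  mu <- apply_insertion(s$wt$sequence, ins)
  expect_identical(substr(mu, 3173, 3240), substr(mu, 3241, 3308))
})

test_that("scaffold sets round-trip through FASTA + manifest", {
  s <- cbs_scaffold_set()
  dir <- withr::local_tempdir()
  files <- write_scaffolds(s, dir)
  fa <- Biostrings::readDNAStringSet(files[["fasta"]])
  expect_equal(unname(width(fa)), c(5000L, 5068L))
  expect_equal(names(fa), c("CBS_WT", "CBS_MU"))

  manifest <- as.list(read.dcf(files[["manifest"]])[1, ])
  expect_identical(manifest$site_mu_marker, "MU:3210C>G")
  expect_identical(manifest$site_wt_snv, "WT:3184A>G")
  expect_identical(manifest$site_mu_cis_snv, "MU:3252A>G")

  s2 <- read_scaffolds(dir)
  expect_identical(s2$wt$sequence, s$wt$sequence)
  expect_identical(s2$mu$sequence, s$mu$sequence)
  expect_identical(s2$sites, s$sites)
  expect_identical(s2$insertion$divergent_bases, s$insertion$divergent_bases)
  expect_identical(s2$marker$natural_base, "G")
})
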