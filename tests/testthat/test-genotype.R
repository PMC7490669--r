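test_that("competitive pair classification follows the score margin", {
  s <- cbs_scaffold_set()
  wt <- s$wt$sequence
  hap <- apply_insertion(wt, s$insertion)
  snv_hap <- wt
  substr(snv_hap, 3184, 3184) <- "G"

  pairs <- read_pairs(
    c("junction", "shared", "snv_only", "garbage"),
    c(substr(hap, 3100, 3249),      # spans the left insertion junction
      substr(wt, 1000, 1149),       # shared sequence
      substr(snv_hap, 3180, 3329),  # SNV read wholly downstream of the
                                    # breakpoint: one mismatch vs either
      strrep("ACGT", 38)),
    c(revcomp(substr(hap, 3251, 3400)),
      revcomp(substr(wt, 1150, 1299)),
      revcomp(substr(snv_hap, 3330, 3479)),
      strrep("GTCA", 38)))
  ap <- align_pairs(pairs, s)
  expect_identical(classify_pairs(ap),
                   c("MU_STRICT", "TIE", "TIE", "UNMAPPED"))
})

test_that("zygosity thresholds sit exactly at 20% and 80%", {
  pu <- function(frac, depth = 200L) {
    structure(list(depth = depth, alt_fraction = frac),
              class = "pileup_counts")
  }
  expect_identical(call_zygosity(pu(0.50)), "HET")
  expect_identical(call_zygosity(pu(0.80)), "HOM")
  expect_identical(call_zygosity(pu(0.7999)), "HET")
  expect_identical(call_zygosity(pu(0.20)), "HET")
  expect_identical(call_zygosity(pu(0.19)), "ABSENT")
  expect_identical(call_zygosity(pu(1.0)), "HOM")
  expect_identical(call_zygosity(pu(0.5, depth = 14L)), "NOCALL_LOWDEPTH")
})

test_that("the decision table is total, unambiguous and matches the rows", {
  states <- c("ABSENT", "HET", "HOM")
  grid <- expand.grid(wt_snv = states, mu_marker = states,
                      mu_cis_snv = states, stringsAsFactors = FALSE)
  calls <- apply(grid, 1, function(r) resolve_genotype(r)$genotype)
  expect_length(calls, 27L)
  valid <- c("WT", "SNV", "INS", "COMPLEX", "SNV_TRANS_INS",
             "SNV_TRANS_COMPLEX", "INS_TRANS_COMPLEX")
  expect_true(all(calls %in% c(valid, "NO_CALL")))
  expect_setequal(unique(calls), c(valid, "NO_CALL"))
  ## each genotype class arises from a unique signature, except the
  ## SNV-only class which carries het and hom sub-states
  tab <- table(calls[calls != "NO_CALL"])
  expect_equal(unname(tab["SNV"]), 2L)
  expect_true(all(tab[names(tab) != "SNV"] == 1L))

  sig <- function(a, b, c) c(wt_snv = a, mu_marker = b, mu_cis_snv = c)
  expect_identical(resolve_genotype(sig("ABSENT", "HOM", "HOM"))$genotype,
                   "COMPLEX")
  expect_identical(resolve_genotype(sig("ABSENT", "HOM", "HET"))$genotype,
                   "INS_TRANS_COMPLEX")
  expect_identical(resolve_genotype(sig("HOM", "HOM", "ABSENT"))$genotype,
                   "NO_CALL")
  expect_identical(resolve_genotype(sig("HET", "ABSENT", "HOM"))$genotype,
                   "NO_CALL")
  ## a heterozygous marker is never legitimate under the competition
  ## policy: strictly mutant pairs all carry the insertion
  anom <- resolve_genotype(sig("ABSENT", "HET", "ABSENT"))
  expect_identical(anom$genotype, "NO_CALL")
  expect_identical(anom$reason, "anomalous_marker")
  ## low-depth propagation
  expect_identical(
    resolve_genotype(sig("NOCALL_LOWDEPTH", "NOCALL_LOWDEPTH",
                         "NOCALL_LOWDEPTH"))$genotype, "NO_CALL")
  expect_identical(resolve_genotype(sig("HET", "NOCALL_LOWDEPTH",
                                        "NOCALL_LOWDEPTH"))$genotype, "SNV")
})

test_that("marker pileup is pure and silent without the insertion", {
  s <- cbs_scaffold_set()
  prm <- sim_params(base_error_rate = 0, seed = 31L)

  cl <- call_sample(simulate_pairs(make_haplotypes(s, "INS_HET"), prm), s)
  mk <- cl$pileups$mu_marker
  expect_identical(cl$genotype, "INS")
  expect_equal(mk$alt_fraction, 1.0)
  expect_gte(mk$depth, 15L)

  cl_wt <- call_sample(simulate_pairs(make_haplotypes(s, "WT"), prm), s)
  expect_equal(cl_wt$pileups$mu_marker$depth, 0L)
  expect_identical(cl_wt$genotype, "WT")

  ## complex het: strictly-MU pairs at the cis site carry only the alt
  cl_cx <- call_sample(simulate_pairs(make_haplotypes(s, "COMPLEX_HET"),
                                      prm), s)
  expect_equal(cl_cx$pileups$mu_cis_snv$alt_fraction, 1.0)
})

test_that("trans configurations read HET at the wild-type SNV site", {
  s <- cbs_scaffold_set()
  cl <- call_sample(simulate_pairs(make_haplotypes(s, "SNV_TRANS_COMPLEX"),
                                   sim_params(seed = 33L)), s)
  f <- cl$pileups$wt_snv$alt_fraction
  expect_gt(f, 0.20)
  expect_lt(f, 0.80)
  expect_identical(cl$genotype, "SNV_TRANS_COMPLEX")
})

test_that("every genotype/phase combination resolves end to end", {
  s <- cbs_scaffold_set()
  for (g in genotype_labels()) {
    cl <- call_sample(simulate_genotype(s, g, sim_params(seed = 17L)), s)
    expect_identical(cl$genotype, expected_call(g))
    if (g == "SNV_HET") expect_identical(cl$zygosity, "HET")
    if (g == "SNV_HOM") expect_identical(cl$zygosity, "HOM")
  }
})

test_that("the rare insertion allele is genotyped like the common one", {
  s <- cbs_scaffold_set("rare")
  cl <- call_sample(simulate_genotype(s, "COMPLEX_HET",
                                      sim_params(seed = 19L)), s)
  expect_identical(cl$genotype, "COMPLEX")
})

test_that("empty input yields NO_CALL with low-depth sites", {
  s <- cbs_scaffold_set()
  empty <- read_pairs(character(), character(), character())
  cl <- call_sample(empty, s)
  expect_identical(cl$genotype, "NO_CALL")
  expect_true(all(cl$signature == "NOCALL_LOWDEPTH"))

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "e_R1.fastq"); f2 <- file.path(dir, "e_R2.fastq")
  file.create(f1, f2)
  expect_identical(call_sample(c(f1, f2), s)$genotype, "NO_CALL")
})

test_that("single-reference mode suppresses the cis variant allele", {
  s <- cbs_scaffold_set()
  prm <- sim_params(seed = 23L)

  p_cx <- simulate_pairs(make_haplotypes(s, "COMPLEX_HOM"), prm)
  sr <- call_single_reference(p_cx, s)
  expect_lt(sr$pileups$wt_snv$alt_fraction, 0.80)  # wrong or missed
  dual <- call_sample(p_cx, s)
  expect_gte(dual$pileups$mu_cis_snv$alt_fraction, 0.80)
  expect_identical(dual$genotype, "COMPLEX")
  ## suppression is strict: the true allele dosage is 1.0
  expect_lt(sr$pileups$wt_snv$alt_fraction, 1.0)

  p_snv <- simulate_pairs(make_haplotypes(s, "SNV_HOM"), prm)
  sr2 <- call_single_reference(p_snv, s)
  expect_gte(sr2$pileups$wt_snv$alt_fraction, 0.95)
  expect_identical(sr2$signature[["wt_snv"]], "HOM")

  p_wt <- simulate_pairs(make_haplotypes(s, "WT"), prm)
  expect_lt(call_single_reference(p_wt, s)$pileups$wt_snv$alt_fraction, 0.05)
})

test_that("calls round-trip through FASTQ files and the report writer", {
  s <- cbs_scaffold_set()
  p <- simulate_genotype(s, "INS_TRANS_COMPLEX", sim_params(seed = 29L))
  dir <- withr::local_tempdir()
  files <- write_fastq_pairs(p, file.path(dir, "s"))
  cl_file <- call_sample(c(files[1], files[2]), s)
  cl_mem <- call_sample(p, s)
  expect_identical(cl_file$genotype, "INS_TRANS_COMPLEX")
  expect_identical(cl_file$signature, cl_mem$signature)
  expect_identical(cl_file$sites$depth, cl_mem$sites$depth)

  rp <- file.path(dir, "report.tsv")
  write_call_report(cl_file, rp)
  lines <- readLines(rp)
  expect_true(any(grepl("^genotype\tINS_TRANS_COMPLEX$", lines)))
  expect_true(any(grepl("mu_marker", lines)))
})
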