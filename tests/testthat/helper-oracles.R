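suppressPackageStartupMessages(library(Biostrings))

## ---- small synthetic locus (fast fixture for unit tests) -------------------
## 800 bp reference, 30 bp duplication of 401-430 inserted before 401,
## marker at insertion offset 10 (natural G -> scaffold C), SNV at 408.
small_scaffold_set <- function() {
  seq <- withr::with_seed(4242L, {
    s <- strsplit(paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                        collapse = ""), "")[[1]]
    s[408] <- "A"
    s[410] <- "G"
    paste(s, collapse = "")
  })
  ref <- reference_region("TOY_WT", seq)
  src <- substr(seq, 401, 430)
  div_off <- c(3L, 22L)
  div_base <- vapply(div_off, function(o) {
    b <- substr(src, o, o)
    c(A = "C", C = "A", G = "T", T = "G")[[b]]
  }, character(1))
  ins <- insertion_spec(401L, 430L, 401L, div_off, div_base)
  build_scaffolds(ref, ins, marker_spec(10L, "C"), snv_spec(408L, "A", "G"),
                  mu_name = "TOY_MU")
}

## ---- exhaustive affine-gap local DP (pure R, test-only) --------------------
r_local_affine <- function(read, ref, match = 1, mismatch = -4,
                           gap_open = -6, gap_ext = -1) {
  x <- strsplit(read, "")[[1]]
  y <- strsplit(ref, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_ext)
      F_[i, j] <- max(H[i - 1, j] + gap_open, F_[i - 1, j] + gap_ext)
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

## ---- independent DP oracle via Biostrings ----------------------------------
## gapOpening 5 / gapExtension 1 reproduces gap_open -6 + (L-1)*(-1)
bs_submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                          baseOnly = TRUE)
bs_local_score <- function(read, ref) {
  score(pairwiseAlignment(DNAString(read), DNAString(ref),
                          substitutionMatrix = bs_submat,
                          gapOpening = 5, gapExtension = 1, type = "local"))
}

## ---- brute-force two-sided Fisher over the hypergeometric support ----------
## exact binomial coefficients through choose(); independent of fisher.test
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1.0)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), 0)
  p_obs <- prob[ks == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

## mate intervals from simulation truth, for raw-coverage arithmetic
mate_cover_count <- function(pairs, hap_idx, pos, read_length = 150L) {
  p <- pairs[pairs$hap == hap_idx, ]
  m1 <- p$frag_start <= pos & pos <= p$frag_start + read_length - 1L
  m2 <- p$frag_end - read_length + 1L <= pos & pos <= p$frag_end
  sum(m1) + sum(m2)
}
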