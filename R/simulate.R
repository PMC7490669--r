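GENOTYPE_LABELS <- c("WT", "SNV_HET", "SNV_HOM", "INS_HET", "INS_HOM",
                     "COMPLEX_HET", "COMPLEX_HOM", "SNV_TRANS_INS",
                     "SNV_TRANS_COMPLEX", "INS_TRANS_COMPLEX")

#' Diploid genotype / phase combinations
#'
#' The genotype labels describe both haplotypes of a sample with respect
#' to the SNV and the insertion allele: `COMPLEX` means SNV and
#' insertion in cis on one chromosome; the `*_TRANS_*` labels are the
#' compound configurations with the two named alleles on opposite
#' chromosomes.
#'
#' @param label One of `genotype_labels()`.
#' @return An object of class `diploid_genotype` with two per-haplotype
#'   descriptors (`has_insertion`, `has_snv`).
#' @export
diploid_genotype <- function(label) {
  hap <- function(ins = FALSE, snv = FALSE)
    list(has_insertion = ins, has_snv = snv)
  haps <- switch(label,
    WT = list(hap(), hap()),
    SNV_HET = list(hap(snv = TRUE), hap()),
    SNV_HOM = list(hap(snv = TRUE), hap(snv = TRUE)),
    INS_HET = list(hap(ins = TRUE), hap()),
    INS_HOM = list(hap(ins = TRUE), hap(ins = TRUE)),
    COMPLEX_HET = list(hap(ins = TRUE, snv = TRUE), hap()),
    COMPLEX_HOM = list(hap(ins = TRUE, snv = TRUE),
                       hap(ins = TRUE, snv = TRUE)),
    SNV_TRANS_INS = list(hap(snv = TRUE), hap(ins = TRUE)),
    SNV_TRANS_COMPLEX = list(hap(snv = TRUE), hap(ins = TRUE, snv = TRUE)),
    INS_TRANS_COMPLEX = list(hap(ins = TRUE),
                             hap(ins = TRUE, snv = TRUE)),
    stop("unknown genotype label: ", label, call. = FALSE))
  structure(list(label = label, haplotypes = haps), class = "diploid_genotype")
}

#' @rdname diploid_genotype
#' @export
genotype_labels <- function() GENOTYPE_LABELS

#' The seven resolvable genotype classes
#'
#' One simulated representative per row of the genotype/phase lookup
#' table (heterozygous representatives where the table does not
#' distinguish zygosity).
#'
#' @return Character vector of 7 genotype labels.
#' @export
table1_genotypes <- function() {
  c("SNV_HET", "INS_HET", "COMPLEX_HET", "SNV_TRANS_INS",
    "SNV_TRANS_COMPLEX", "INS_TRANS_COMPLEX", "WT")
}

#' Expected caller output for a simulated truth genotype
#'
#' Maps a simulation truth label to the genotype class the dual-scaffold
#' caller reports (the caller does not resolve insertion zygosity, so
#' het and hom insertion/complex carriers share a class; the SNV-only
#' class carries its zygosity as a sub-label).
#'
#' @param label A [genotype_labels()] value.
#' @return The expected `genotype` field of a call.
#' @export
expected_call <- function(label) {
  switch(label,
    SNV_HET = , SNV_HOM = "SNV",
    INS_HET = , INS_HOM = "INS",
    COMPLEX_HET = , COMPLEX_HOM = "COMPLEX",
    label)
}

#' Read-simulation parameters
#'
#' Defaults emulate the simulation conditions of the study: 200-fold
#' coverage of 150 bp paired-end reads with fragment lengths
#' Normal(300, 100) and a uniform per-base substitution error rate of
#' 0.1% (an Illumina-like error magnitude; indel errors are not
#' simulated).
#'
#' @param coverage Fold coverage of the diploid sample.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment-length distribution (bp).
#' @param base_error_rate Per-base substitution error probability.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   byte-identical reads.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(coverage = 200, read_length = 150L,
                       fragment_mean = 300, fragment_sd = 100,
                       base_error_rate = 0.001, seed = 1L) {
  read_length <- as.integer(read_length)
  stopifnot(coverage > 0, read_length >= 1L, fragment_mean > 0,
            fragment_sd >= 0, base_error_rate >= 0, base_error_rate < 1)
  if (read_length > fragment_mean + 4 * fragment_sd)
    stop("read length exceeds fragment_mean + 4*fragment_sd", call. = FALSE)
  structure(list(coverage = coverage, read_length = read_length,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_error_rate = base_error_rate, seed = as.integer(seed)),
            class = "sim_params")
}

#' Construct the two haplotype sequences of a genotype
#'
#' Each haplotype starts from the wild-type sequence; insertion-bearing
#' haplotypes receive the natural insertion allele (divergent bases
#' applied, natural base at the marker offset -- the engineered scaffold
#' base never occurs in simulated molecules); SNV-bearing haplotypes
#' receive the alternate base at the SNV position, which on
#' insertion-bearing (cis) haplotypes lies downstream of the insertion,
#' at the position lifting to the mutant scaffold's cis readout site.
#'
#' @param sset A `scaffold_set`.
#' @param genotype A [diploid_genotype()] or genotype label.
#' @return Named character vector of the two haplotype sequences.
#' @export
make_haplotypes <- function(sset, genotype) {
  stopifnot(inherits(sset, "scaffold_set"))
  if (is.character(genotype)) genotype <- diploid_genotype(genotype)
  one <- function(h) {
    if (h$has_insertion) {
      seq <- apply_insertion(sset$wt$sequence, sset$insertion, marker = NULL)
      if (h$has_snv) {
        pos <- lift_coordinate(sset, "WT", sset$snv$wt_position)
        substr(seq, pos, pos) <- sset$snv$alt_base
      }
    } else {
      seq <- sset$wt$sequence
      if (h$has_snv) {
        pos <- sset$snv$wt_position
        substr(seq, pos, pos) <- sset$snv$alt_base
      }
    }
    seq
  }
  stats::setNames(vapply(genotype$haplotypes, one, character(1)),
                  paste0("hap", 1:2))
}

phred_char <- function(error_rate) {
  q <- if (error_rate <= 0) 40L else as.integer(round(-10 * log10(error_rate)))
  q <- max(2L, min(40L, q))
  intToUtf8(q + 33L)
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs[1])
  nerr <- rbinom(length(seqs), rl, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(rl, nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Simulate diploid paired-end reads
#'
#' Draws `round(mean(len) * coverage / (2 * read_length))` fragments,
#' assigning each to a haplotype by a fair coin; fragment lengths are
#' Normal(mean, sd) redrawn until they fall within
#' `[read_length, haplotype length]` (never truncated, so mates cannot
#' run off the fragment), fragment starts are uniform, and substitution
#' errors are independent per base with a random non-identical
#' replacement.  Base qualities are constant at the Phred value matching
#' the error rate.  Mate 2 is the reverse complement of the fragment
#' end.  Deterministic under a fixed seed (the caller's RNG state is
#' left untouched).
#'
#' @param haplotypes Character vector of 1 or 2 haplotype sequences.
#' @param params A [sim_params()].
#' @return A `read_pairs` data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` and truth columns `hap`, `frag_start`, `frag_end`.
#' @export
simulate_pairs <- function(haplotypes, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  haplotypes <- as.character(haplotypes)
  nh <- length(haplotypes)
  stopifnot(nh %in% 1:2)
  lens <- nchar(haplotypes)
  rl <- params$read_length
  if (any(lens < rl))
    stop("haplotype shorter than the read length", call. = FALSE)
  with_preserved_rng({
    set.seed(params$seed)
    npairs <- max(1L, as.integer(round(
      mean(lens) * params$coverage / (2 * rl))))
    hap <- if (nh == 2L) sample(1:2, npairs, replace = TRUE)
           else rep(1L, npairs)
    frag <- as.integer(round(rnorm(npairs, params$fragment_mean,
                                   params$fragment_sd)))
    bad <- which(frag < rl | frag > lens[hap])
    tries <- 0L
    while (length(bad) && (tries <- tries + 1L) < 1000L) {
      frag[bad] <- as.integer(round(rnorm(length(bad), params$fragment_mean,
                                          params$fragment_sd)))
      bad <- which(frag < rl | frag > lens[hap])
    }
    if (length(bad))
      stop("could not sample valid fragment lengths", call. = FALSE)
    start <- as.integer(floor(runif(npairs, 1, lens[hap] - frag + 2)))
    end <- start + frag - 1L
    hseq <- haplotypes[hap]
    seq1 <- substring(hseq, start, start + rl - 1L)
    seq2 <- revcomp(substring(hseq, end - rl + 1L, end))
    seq1 <- inject_errors(seq1, params$base_error_rate)
    seq2 <- inject_errors(seq2, params$base_error_rate)
    qual <- strrep(phred_char(params$base_error_rate), rl)
    structure(
      data.frame(id = sprintf("sim_%06d", seq_len(npairs)),
                 seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual,
                 hap = hap, frag_start = start, frag_end = end,
                 stringsAsFactors = FALSE),
      class = c("read_pairs", "data.frame"))
  })
}

#' Simulate reads for a genotype on a scaffold set
#'
#' Convenience wrapper: [make_haplotypes()] then [simulate_pairs()].
#' Warns when the read length does not exceed the insertion length,
#' since the marker-coverage guarantee (every insertion read covering
#' the marker spans a junction) then no longer holds.
#'
#' @param sset A `scaffold_set`.
#' @param genotype Genotype label or [diploid_genotype()].
#' @param params A [sim_params()].
#' @return A `read_pairs` data.frame.
#' @export
simulate_genotype <- function(sset, genotype, params = sim_params()) {
  if (params$read_length <= sset$insertion$length)
    warning("read length does not exceed the insertion length; ",
            "insertion reads may cover the marker without spanning a junction")
  simulate_pairs(make_haplotypes(sset, genotype), params)
}

#' Construct a read-pairs object
#'
#' @param id Read identifiers (without mate suffixes).
#' @param seq1,seq2 Mate sequences.
#' @param qual1,qual2 Phred+33 quality strings (defaults to Q40).
#' @return A `read_pairs` data.frame.
#' @export
read_pairs <- function(id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
  structure(data.frame(id = as.character(id), seq1 = seq1, qual1 = qual1,
                       seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

#' Write read pairs as paired FASTQ
#'
#' Emits `<prefix>_R1.fastq` / `<prefix>_R2.fastq` (Phred+33, mate
#' suffixes `/1` and `/2`) and, when truth columns are present, a
#' tab-separated truth sidecar `<prefix>_truth.tsv`.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  files <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    x <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(x) <- paste0(pairs$id, "/", m)
    Biostrings::writeXStringSet(
      x, filepath = files[m], format = "fastq",
      qualities = Biostrings::BStringSet(pairs[[paste0("qual", m)]]))
  }
  out <- files
  if (all(c("hap", "frag_start", "frag_end") %in% names(pairs))) {
    truth <- paste0(prefix, "_truth.tsv")
    write.table(pairs[, c("id", "hap", "frag_start", "frag_end")],
                truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(files, truth)
  }
  invisible(out)
}

#' Read paired FASTQ files
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `read_pairs` data.frame.
#' @export
read_fastq_pairs <- function(r1, r2) {
  rd <- function(path, m) {
    ## Biostrings warns about dropping its own internal metadata column
    ## when pairing sequences with qualities; harmless here
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    id <- sub("[/ ].*$", "", names(x))
    q <- as.character(Biostrings::quality(x))
    if (length(x) == 0L) q <- character()
    stats::setNames(
      data.frame(id = id, seq = as.character(x), qual = q,
                 stringsAsFactors = FALSE),
      c("id", paste0("seq", m), paste0("qual", m)))
  }
  a <- rd(r1, 1L); b <- rd(r2, 2L)
  if (nrow(a) != nrow(b) || (nrow(a) && !all(a$id == b$id)))
    stop("mate files disagree on read ids", call. = FALSE)
  structure(cbind(a, b[, -1, drop = FALSE]),
            class = c("read_pairs", "data.frame"))
}
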