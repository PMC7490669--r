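#' Alignment scoring scheme
#'
#' Parameters of the seed-and-extend affine-gap aligner.  Terminal soft
#' clips are free (clipped bases score 0), so a gap of length L costs
#' `gap_open + (L-1) * gap_extend`.  The defaults (+1/-4/-6/-1) make one
#' 68 bp gap (-73) costlier than four mismatches (-16), which forces
#' reads lacking the insertion to soft-clip at the breakpoints instead
#' of opening the gap -- the behaviour that drives the competitive
#' scaffold classification.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Penalty of the first gapped base (<= `gap_extend`).
#' @param gap_extend Penalty per additional gapped base (< 0).
#' @param min_anchor Minimum aligned (non-clipped) read bases for a
#'   placement to count as mapped.
#' @param k Seed length for the exact k-mer index (>= 8).
#' @param max_clusters Number of seed-diagonal clusters extended per
#'   read and strand.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L, min_anchor = 25L, k = 15L,
                           max_clusters = 4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(match > 0L, mismatch < 0L, gap_extend < 0L,
            gap_open <= gap_extend, min_anchor >= 1L, k >= 8L,
            max_clusters >= 1L)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_anchor = as.integer(min_anchor),
                 k = as.integer(k), max_clusters = as.integer(max_clusters)),
            class = "scoring_scheme")
}

region_sequence <- function(x) {
  if (inherits(x, "reference_region")) x$sequence
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a reference_region or a sequence string", call. = FALSE)
}

#' Exact k-mer seed index
#'
#' Positions of every exact k-mer occurrence on a reference, the seeding
#' structure of the aligner.  Returned as a closure-backed object whose
#' `lookup(kmer)` gives all 1-based occurrence positions.
#'
#' @param region A [reference_region()] or sequence string.
#' @param k Seed length; values below 8 are rejected (seeds would lose
#'   specificity).
#' @return An object of class `seed_index` with elements `k` and
#'   `lookup`.
#' @export
seed_index <- function(region, k = 15L) {
  seq <- region_sequence(region)
  k <- as.integer(k)
  if (k < 8L) stop("seed length k must be at least 8", call. = FALSE)
  if (k > nchar(seq)) stop("k exceeds the reference length", call. = FALSE)
  structure(list(
    k = k,
    lookup = function(kmer) {
      stopifnot(nchar(kmer) == k)
      hits <- gregexpr(paste0("(?=", kmer, ")"), seq, perl = TRUE)[[1]]
      as.integer(hits[hits > 0L])
    }), class = "seed_index")
}

default_band <- function(expected_indel = 0L) {
  max(16L, as.integer(expected_indel)) + 4L
}

#' Align reads to one reference
#'
#' Seed-and-extend alignment of each read (both orientations) against a
#' single reference, with banded affine-gap extension and free terminal
#' soft clips.  Ties are broken deterministically: higher score, then
#' lower reference start, then smaller left clip, forward strand
#' preferred.
#'
#' @param seqs Character vector of read sequences.
#' @param region A [reference_region()] or sequence string.
#' @param scheme A [scoring_scheme()].
#' @param sites Integer reference positions at which to report the
#'   aligned read base (columns `base_<pos>` / `dist_<pos>`, where the
#'   distance is the number of aligned read bases between the reported
#'   base and the nearer end of the aligned segment).
#' @param band Half-width of the extension band around the seed
#'   diagonal; defaults to `max(16, expected_indel) + 4`.
#' @param expected_indel Largest indel the band must span (e.g. the
#'   insertion length when aligning against the mutant scaffold pair).
#' @param try_revcomp Also try the reverse-complement orientation.
#' @return A data.frame with one row per read: `mapped`, `score`,
#'   `start`, `end`, `left_clip`, `right_clip`, `n_aligned`, `strand`,
#'   `cigar`, plus the per-site columns.
#' @export
align_reads <- function(seqs, region, scheme = scoring_scheme(),
                        sites = integer(), band = NULL,
                        expected_indel = 0L, try_revcomp = TRUE) {
  seq <- region_sequence(region)
  if (is.null(band)) band <- default_band(expected_indel)
  sites <- as.integer(sites)
  res <- cpp_align_batch(as.character(seqs), seq, scheme$k, scheme$match,
                         scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                         as.integer(band), scheme$min_anchor, sites,
                         isTRUE(try_revcomp), scheme$max_clusters)
  out <- data.frame(mapped = res$mapped, score = res$score, start = res$start,
                    end = res$end, left_clip = res$left_clip,
                    right_clip = res$right_clip, n_aligned = res$n_aligned,
                    strand = res$strand, cigar = res$cigar,
                    stringsAsFactors = FALSE)
  if (length(sites)) {
    sb <- res$site_base; sd_ <- res$site_dist; sq <- res$site_qpos
    for (i in seq_along(sites)) {
      out[[paste0("base_", sites[i])]] <- as.character(sb[, i])
      out[[paste0("dist_", sites[i])]] <- as.integer(sd_[, i])
      out[[paste0("qpos_", sites[i])]] <- as.integer(sq[, i])
    }
  }
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @inheritParams align_reads
#' @param seq Read sequence.
#' @return A one-row data.frame (see [align_reads()]).
#' @export
align_read <- function(seq, region, scheme = scoring_scheme(), sites = integer(),
                       band = NULL, expected_indel = 0L, try_revcomp = TRUE) {
  align_reads(seq, region, scheme, sites, band, expected_indel, try_revcomp)
}

#' Align read pairs against both scaffolds
#'
#' Aligns both mates of every pair independently to the wild-type and
#' mutant scaffolds and combines them into per-scaffold pair placements:
#' the pair score is the sum of the mate scores (`NA` when either mate
#' is unmapped on that scaffold), and a proper-pair flag records
#' forward/reverse orientation with an insert length within
#' `frag_mean + c(-4, 4) * frag_sd`.
#'
#' @param pairs A [read_pairs()] object (or data.frame with columns
#'   `id`, `seq1`, `seq2`).
#' @param sset A `scaffold_set` from [build_scaffolds()].
#' @param scheme A [scoring_scheme()].
#' @param frag_mean,frag_sd Fragment-length model used for the
#'   proper-pair gate.
#' @return A list with elements `wt` and `mu`; each contains `mate1` and
#'   `mate2` alignment data.frames (with site columns for that
#'   scaffold's informative sites), `pair_score`, and `proper`.
#' @export
align_pairs <- function(pairs, sset, scheme = scoring_scheme(),
                        frag_mean = 300, frag_sd = 100) {
  stopifnot(inherits(sset, "scaffold_set"))
  band <- default_band(sset$insertion$length)
  sites_wt <- sset$sites$wt_snv
  sites_mu <- c(sset$sites$mu_marker, sset$sites$mu_cis_snv)
  one <- function(region, sites) {
    m1 <- align_reads(pairs$seq1, region, scheme, sites, band = band)
    m2 <- align_reads(pairs$seq2, region, scheme, sites, band = band)
    pair_score <- ifelse(m1$mapped & m2$mapped, m1$score + m2$score,
                         NA_integer_)
    insert <- pmax(m1$end, m2$end) - pmin(m1$start, m2$start) + 1L
    fr <- m1$strand != m2$strand &
      ifelse(m1$start <= m2$start, m1$strand == 1L, m2$strand == 1L)
    proper <- !is.na(pair_score) & fr &
      insert >= max(1, frag_mean - 4 * frag_sd) &
      insert <= frag_mean + 4 * frag_sd
    list(mate1 = m1, mate2 = m2, pair_score = pair_score,
         proper = proper & !is.na(proper))
  }
  list(wt = one(sset$wt, sites_wt), mu = one(sset$mu, sites_mu))
}

cigar_runs <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  list(lens = lens, ops = ops)
}

#' Recompute an alignment score from its CIGAR operations
#'
#' Rebuilds the score of a placement by replaying its CIGAR against the
#' reference (soft clips free, affine gaps), a consistency check that
#' the reported score matches the reported operations.
#'
#' @param seq Read sequence as aligned (i.e. reverse-complemented
#'   beforehand for minus-strand placements).
#' @param region Reference the read was placed on.
#' @param start 1-based reference start of the aligned segment.
#' @param cigar CIGAR string with M/I/D/S operations.
#' @param scheme A [scoring_scheme()].
#' @return The recomputed integer score.
#' @export
score_from_cigar <- function(seq, region, start, cigar,
                             scheme = scoring_scheme()) {
  ref <- region_sequence(region)
  runs <- cigar_runs(cigar)
  i <- 1L; j <- as.integer(start); sc <- 0L
  for (r in seq_along(runs$ops)) {
    len <- runs$lens[r]
    switch(runs$ops[r],
      S = { i <- i + len },
      M = {
        a <- seq_chars(substr(seq, i, i + len - 1L))
        b <- seq_chars(substr(ref, j, j + len - 1L))
        sc <- sc + sum(a == b) * scheme$match + sum(a != b) * scheme$mismatch
        i <- i + len; j <- j + len
      },
      I = {
        sc <- sc + scheme$gap_open + (len - 1L) * scheme$gap_extend
        i <- i + len
      },
      D = {
        sc <- sc + scheme$gap_open + (len - 1L) * scheme$gap_extend
        j <- j + len
      })
  }
  sc
}

#' Exhaustive affine-gap local alignment score (reference path)
#'
#' Full-matrix Smith-Waterman/Gotoh score of a read against a
#' reference, with no seeding, banding or heuristics.  Used as the
#' slow reference implementation the seed-and-extend aligner is
#' checked against.
#'
#' @param seq Read sequence.
#' @param region A [reference_region()] or sequence string.
#' @param scheme A [scoring_scheme()] (only the substitution and gap
#'   parameters are used; clips are free as in the heuristic aligner).
#' @return The integer optimal local alignment score.
#' @export
align_full_score <- function(seq, region, scheme = scoring_scheme()) {
  ref <- region_sequence(region)
  vapply(as.character(seq), function(s)
    cpp_align_full_score(s, ref, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend),
    integer(1), USE.NAMES = FALSE)
}
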