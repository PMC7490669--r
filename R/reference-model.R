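#' @useDynLib scafphase, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fisher.test rnorm runif rbinom setNames
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## strsplit to single characters, the workhorse representation for
## position-level edits on scaffold-sized (kb) sequences
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop(what, " may contain only uppercase A/C/G/T (ambiguity codes rejected)",
         call. = FALSE)
  invisible(sequence)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' A reference region
#'
#' A named stretch of genomic sequence, optionally anchored to a genome
#' assembly so that region position `p` corresponds to genome position
#' `anchor_start + p - 1`.
#'
#' @param name Sequence name (used as the FASTA record name).
#' @param sequence Uppercase A/C/G/T string.
#' @param anchor_chrom,anchor_start Optional genomic anchor (chromosome
#'   name and 1-based start of region position 1).
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(name, sequence, anchor_chrom = NULL,
                             anchor_start = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_dna(sequence)
  if (!is.null(anchor_start)) {
    anchor_start <- as.integer(anchor_start)
    stopifnot(length(anchor_start) == 1L, anchor_start >= 1L)
  }
  structure(
    list(name = name, sequence = sequence,
         anchor_chrom = anchor_chrom, anchor_start = anchor_start),
    class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat("<reference_region> ", x$name, ": ", nchar(x$sequence), " bp", sep = "")
  if (!is.null(x$anchor_start))
    cat(" [", x$anchor_chrom, ":", format(x$anchor_start, big.mark = ","),
        "-", format(x$anchor_start + nchar(x$sequence) - 1L, big.mark = ","),
        "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Map a region position to genome coordinates
#'
#' @param region A [reference_region()] with a genomic anchor.
#' @param pos 1-based position(s) within the region.
#' @return Integer genome position(s).
#' @export
genomic_position <- function(region, pos) {
  if (is.null(region$anchor_start))
    stop("region has no genomic anchor", call. = FALSE)
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1L), all(pos <= nchar(region$sequence)))
  region$anchor_start + pos - 1L
}

#' Specification of a (near-)tandem duplication insertion allele
#'
#' Describes an insertion allele as a copy of a source interval of the
#' wild-type sequence, inserted immediately before `insertion_point`,
#' with a small number of bases diverging from the copied template.
#'
#' @param source_start,source_end 1-based closed interval on the
#'   wild-type sequence that is duplicated.
#' @param insertion_point Wild-type position immediately before which
#'   the copy is inserted.
#' @param divergent_offsets Integer offsets (1-based, within the
#'   insertion) at which the copy differs from the template.
#' @param divergent_bases Replacement bases, same length as
#'   `divergent_offsets`; each must differ from the copied base (checked
#'   at build time against the reference).
#' @param allele Allele label, e.g. `"common"` or `"rare"`.
#' @return An object of class `insertion_spec`.
#' @export
insertion_spec <- function(source_start, source_end, insertion_point,
                           divergent_offsets = integer(),
                           divergent_bases = character(),
                           allele = "common") {
  source_start <- as.integer(source_start)
  source_end <- as.integer(source_end)
  insertion_point <- as.integer(insertion_point)
  divergent_offsets <- as.integer(divergent_offsets)
  stopifnot(source_start >= 1L, source_end >= source_start,
            insertion_point >= 1L,
            length(divergent_offsets) == length(divergent_bases))
  len <- source_end - source_start + 1L
  if (length(divergent_offsets)) {
    if (any(divergent_offsets < 1L | divergent_offsets > len))
      stop("divergent offsets must lie within [1, insertion length]",
           call. = FALSE)
    if (anyDuplicated(divergent_offsets))
      stop("duplicated divergent offsets", call. = FALSE)
    if (!all(divergent_bases %in% DNA_BASES))
      stop("divergent bases must be A/C/G/T", call. = FALSE)
  }
  structure(
    list(source_start = source_start, source_end = source_end,
         insertion_point = insertion_point, length = len,
         divergent_offsets = divergent_offsets,
         divergent_bases = divergent_bases, allele = allele),
    class = "insertion_spec")
}

#' Engineered marker base specification
#'
#' The mutant scaffold carries a deliberately altered base at a
#' conserved offset inside the inserted copy.  Reads from real insertion
#' alleles carry the natural base there, so every insertion-bearing read
#' covering the offset produces a predictable mismatch against the
#' mutant scaffold -- a "predetermined variant call" marking the
#' insertion.
#'
#' @param insertion_offset 1-based offset within the inserted copy.
#' @param scaffold_base Base written into the mutant scaffold.
#' @param natural_base Base carried by real insertion alleles at the
#'   offset; if `NULL`, filled in from the copied template at build time.
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(insertion_offset, scaffold_base, natural_base = NULL) {
  insertion_offset <- as.integer(insertion_offset)
  stopifnot(insertion_offset >= 1L, scaffold_base %in% DNA_BASES)
  if (!is.null(natural_base)) {
    stopifnot(natural_base %in% DNA_BASES)
    if (natural_base == scaffold_base)
      stop("marker scaffold base must differ from the natural base",
           call. = FALSE)
  }
  structure(
    list(insertion_offset = insertion_offset, scaffold_base = scaffold_base,
         natural_base = natural_base),
    class = "marker_spec")
}

#' Single-nucleotide variant specification
#'
#' @param wt_position 1-based position on the wild-type scaffold.
#' @param ref_base,alt_base Reference and alternate base (plus strand).
#' @return An object of class `snv_spec`.
#' @export
snv_spec <- function(wt_position, ref_base, alt_base) {
  wt_position <- as.integer(wt_position)
  stopifnot(wt_position >= 1L, ref_base %in% DNA_BASES,
            alt_base %in% DNA_BASES, ref_base != alt_base)
  structure(list(wt_position = wt_position, ref_base = ref_base,
                 alt_base = alt_base), class = "snv_spec")
}

#' Apply a tandem-duplication insertion to a reference sequence
#'
#' Low-level constructor of the mutant allele string:
#' `ref[1..ins_point-1] + copy + ref[ins_point..end]`, where `copy` is
#' the source interval with divergent bases applied and, optionally, the
#' marker scaffold base written in.
#'
#' @param ref_seq Wild-type sequence string.
#' @param ins An [insertion_spec()].
#' @param marker Optional [marker_spec()]; when `NULL` the natural copy
#'   is inserted (perfect near-tandem duplication).
#' @return The mutant sequence string.
#' @export
apply_insertion <- function(ref_seq, ins, marker = NULL) {
  assert_dna(ref_seq)
  n <- nchar(ref_seq)
  if (ins$source_end > n || ins$insertion_point > n + 1L)
    stop("insertion spec exceeds the reference", call. = FALSE)
  copy <- seq_chars(substr(ref_seq, ins$source_start, ins$source_end))
  if (length(ins$divergent_offsets)) {
    same <- copy[ins$divergent_offsets] == ins$divergent_bases
    if (any(same))
      stop("divergent base equals the copied base at offset ",
           paste(ins$divergent_offsets[same], collapse = ","), call. = FALSE)
    copy[ins$divergent_offsets] <- ins$divergent_bases
  }
  if (!is.null(marker)) {
    if (marker$insertion_offset > ins$length)
      stop("marker offset lies outside the inserted copy", call. = FALSE)
    if (marker$insertion_offset %in% ins$divergent_offsets)
      stop("divergent offset collides with the marker offset", call. = FALSE)
    if (copy[marker$insertion_offset] == marker$scaffold_base)
      stop("marker scaffold base equals the copied base: ",
           "no expected mismatch is possible", call. = FALSE)
    copy[marker$insertion_offset] <- marker$scaffold_base
  }
  paste0(substr(ref_seq, 1L, ins$insertion_point - 1L),
         paste(copy, collapse = ""),
         substr(ref_seq, ins$insertion_point, n))
}

#' Build a wild-type/mutant scaffold pair
#'
#' Constructs the two competitive-alignment scaffolds for an insertion
#' allele: the wild-type scaffold is the reference region unchanged; the
#' mutant scaffold additionally carries the inserted copy (divergent
#' bases applied, then the engineered marker base).  The returned set
#' records the three informative sites used for genotyping: the SNV
#' position on the wild-type scaffold, the marker position on the mutant
#' scaffold, and the image of the SNV position downstream of the
#' insertion on the mutant scaffold (the cis-configuration readout).
#'
#' @param ref A [reference_region()].
#' @param ins An [insertion_spec()].
#' @param marker A [marker_spec()].
#' @param snv An [snv_spec()].
#' @param mu_name Name for the mutant scaffold record; default derives
#'   from `ref$name`.
#' @return An object of class `scaffold_set` with elements `wt`, `mu`
#'   ([reference_region()]s), `insertion`, `marker`, `snv`, and `sites`
#'   (named positions `wt_snv`, `mu_marker`, `mu_cis_snv`).
#' @examples
#' s <- cbs_scaffold_set()
#' s$sites
#' @export
build_scaffolds <- function(ref, ins, marker, snv,
                            mu_name = paste0(ref$name, "_MU")) {
  stopifnot(inherits(ref, "reference_region"), inherits(ins, "insertion_spec"),
            inherits(marker, "marker_spec"), inherits(snv, "snv_spec"))
  n <- nchar(ref$sequence)
  if (ins$source_end > n)
    stop("source interval outside the reference", call. = FALSE)
  if (snv$wt_position > n)
    stop("SNV position outside the reference", call. = FALSE)
  ## near-tandem: the copy lands adjacent to (or within one copy-length
  ## of) its source, the geometry that creates the duplication ambiguity
  if (ins$insertion_point < ins$source_start - ins$length ||
      ins$insertion_point > ins$source_end + ins$length + 1L)
    stop("insertion point is not tandem-compatible with the source interval",
         call. = FALSE)
  natural <- substr(ref$sequence,
                    ins$source_start + marker$insertion_offset - 1L,
                    ins$source_start + marker$insertion_offset - 1L)
  if (is.null(marker$natural_base)) {
    marker$natural_base <- natural
  } else if (marker$natural_base != natural) {
    stop("declared natural marker base (", marker$natural_base,
         ") does not match the copied template base (", natural, ")",
         call. = FALSE)
  }
  if (marker$scaffold_base == natural)
    stop("marker scaffold base equals the natural copied base: ",
         "no expected mismatch is possible", call. = FALSE)
  ref_base <- substr(ref$sequence, snv$wt_position, snv$wt_position)
  if (ref_base != snv$ref_base)
    stop("SNV ref base (", snv$ref_base, ") does not match the reference (",
         ref_base, ") at position ", snv$wt_position, call. = FALSE)

  mu_seq <- apply_insertion(ref$sequence, ins, marker)
  sites <- list(
    wt_snv = snv$wt_position,
    mu_marker = ins$insertion_point - 1L + marker$insertion_offset,
    mu_cis_snv = if (snv$wt_position >= ins$insertion_point)
      snv$wt_position + ins$length else snv$wt_position)
  structure(
    list(wt = ref,
         mu = reference_region(mu_name, mu_seq,
                               anchor_chrom = ref$anchor_chrom,
                               anchor_start = ref$anchor_start),
         insertion = ins, marker = marker, snv = snv, sites = sites),
    class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("<scaffold_set>\n")
  cat("  WT: ", x$wt$name, " (", nchar(x$wt$sequence), " bp)\n", sep = "")
  cat("  MU: ", x$mu$name, " (", nchar(x$mu$sequence), " bp, +",
      x$insertion$length, " bp insertion before WT:",
      x$insertion$insertion_point, ")\n", sep = "")
  cat("  informative sites: WT:", x$sites$wt_snv, x$snv$ref_base, ">",
      x$snv$alt_base, "  MU:", x$sites$mu_marker, x$marker$scaffold_base, ">",
      x$marker$natural_base, " (marker)  MU:", x$sites$mu_cis_snv,
      x$snv$ref_base, ">", x$snv$alt_base, " (cis)\n", sep = "")
  invisible(x)
}

#' Lift a position between the two scaffolds
#'
#' Positions upstream of the insertion point map to themselves;
#' wild-type positions at or downstream of it shift by the insertion
#' length.  Mutant-scaffold positions inside the inserted copy have no
#' wild-type image and return `NA`.
#'
#' @param s A [build_scaffolds()] result.
#' @param from `"WT"` or `"MU"`: scaffold of the input positions.
#' @param pos Integer position(s) on the `from` scaffold.
#' @return Integer position(s) on the other scaffold (`NA` where no
#'   image exists).
#' @examples
#' s <- cbs_scaffold_set()
#' lift_coordinate(s, "WT", 3184)  # 3252
#' @export
lift_coordinate <- function(s, from = c("WT", "MU"), pos) {
  from <- match.arg(from)
  pos <- as.integer(pos)
  ip <- s$insertion$insertion_point
  len <- s$insertion$length
  if (from == "WT") {
    if (any(pos < 1L | pos > nchar(s$wt$sequence)))
      stop("position outside the WT scaffold", call. = FALSE)
    ifelse(pos < ip, pos, pos + len)
  } else {
    if (any(pos < 1L | pos > nchar(s$mu$sequence)))
      stop("position outside the MU scaffold", call. = FALSE)
    out <- ifelse(pos < ip, pos, pos - len)
    out[pos >= ip & pos < ip + len] <- NA_integer_
    as.integer(out)
  }
}

#' Are two insertion descriptions equivalent?
#'
#' Insertions inside repeated sequence admit several (position, inserted
#' string) descriptions; this resolves whether two descriptions denote
#' the same allele by applying both to the reference and comparing the
#' resulting strings.  `pos` follows the same convention as
#' [insertion_spec()]: the inserted string is placed immediately before
#' reference position `pos`.
#'
#' @param ref_seq Reference sequence string.
#' @param pos_a,ins_a First description (position, inserted string).
#' @param pos_b,ins_b Second description.
#' @return `TRUE` if the two alleles are identical strings.
#' @export
equivalent_insertion_descriptions <- function(ref_seq, pos_a, ins_a,
                                              pos_b, ins_b) {
  assert_dna(ref_seq)
  n <- nchar(ref_seq)
  if (!nzchar(ins_a) || !nzchar(ins_b))
    stop("empty insertion string", call. = FALSE)
  pos_a <- as.integer(pos_a); pos_b <- as.integer(pos_b)
  if (pos_a < 1L || pos_a > n + 1L || pos_b < 1L || pos_b > n + 1L)
    stop("described position outside the reference", call. = FALSE)
  apply_desc <- function(p, ins)
    paste0(substr(ref_seq, 1L, p - 1L), ins, substr(ref_seq, p, n))
  identical(apply_desc(pos_a, ins_a), apply_desc(pos_b, ins_b))
}

## ---- serialization ---------------------------------------------------------

fasta_write <- function(named_seqs, path) {
  x <- Biostrings::DNAStringSet(named_seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
}

#' Write a scaffold set to a directory
#'
#' Emits `scaffolds.fa` (two records, wild-type first) and a
#' machine-readable sites manifest `sites.dcf` recording the informative
#' positions, their expected ref/alt alleles, the marker semantics and
#' the full insertion specification, so the set round-trips through
#' [read_scaffolds()].
#'
#' @param s A [build_scaffolds()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scaffolds <- function(s, out_dir) {
  stopifnot(inherits(s, "scaffold_set"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  fa <- file.path(out_dir, "scaffolds.fa")
  manifest <- file.path(out_dir, "sites.dcf")
  res <- try(fasta_write(setNames(c(s$wt$sequence, s$mu$sequence),
                                  c(s$wt$name, s$mu$name)), fa),
             silent = TRUE)
  if (inherits(res, "try-error"))
    stop("failed to write FASTA at ", fa, ": ", attr(res, "condition")$message,
         call. = FALSE)
  fields <- c(
    wt_name = s$wt$name, mu_name = s$mu$name,
    anchor_chrom = if (is.null(s$wt$anchor_chrom)) "" else s$wt$anchor_chrom,
    anchor_start = if (is.null(s$wt$anchor_start)) "" else s$wt$anchor_start,
    source_start = s$insertion$source_start,
    source_end = s$insertion$source_end,
    insertion_point = s$insertion$insertion_point,
    insertion_length = s$insertion$length,
    allele = s$insertion$allele,
    divergent_offsets = paste(s$insertion$divergent_offsets, collapse = ","),
    divergent_bases = paste(s$insertion$divergent_bases, collapse = ","),
    marker_offset = s$marker$insertion_offset,
    marker_scaffold_base = s$marker$scaffold_base,
    marker_natural_base = s$marker$natural_base,
    snv_wt_position = s$snv$wt_position,
    snv_ref = s$snv$ref_base, snv_alt = s$snv$alt_base,
    site_wt_snv = paste0("WT:", s$sites$wt_snv, s$snv$ref_base, ">",
                         s$snv$alt_base),
    site_mu_marker = paste0("MU:", s$sites$mu_marker, s$marker$scaffold_base,
                            ">", s$marker$natural_base),
    site_mu_cis_snv = paste0("MU:", s$sites$mu_cis_snv, s$snv$ref_base, ">",
                             s$snv$alt_base))
  write.dcf(t(as.matrix(fields)), file = manifest)
  invisible(c(fasta = fa, manifest = manifest))
}

#' Read a scaffold set written by [write_scaffolds()]
#'
#' @param dir Directory containing `scaffolds.fa` and `sites.dcf`.
#' @return A `scaffold_set`, validated against its invariants (the
#'   mutant record must equal the reconstruction from the wild-type
#'   record and the manifest).
#' @export
read_scaffolds <- function(dir) {
  fa <- file.path(dir, "scaffolds.fa")
  manifest <- file.path(dir, "sites.dcf")
  if (!file.exists(fa) || !file.exists(manifest))
    stop("no scaffolds.fa / sites.dcf under ", dir, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fa)
  m <- as.list(read.dcf(manifest)[1L, ])
  num <- function(k) as.integer(m[[k]])
  split_csv <- function(x) if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1]] else character()
  ref <- reference_region(
    m$wt_name, as.character(seqs[[m$wt_name]]),
    anchor_chrom = if (nzchar(m$anchor_chrom)) m$anchor_chrom else NULL,
    anchor_start = if (nzchar(m$anchor_start)) num("anchor_start") else NULL)
  ins <- insertion_spec(num("source_start"), num("source_end"),
                        num("insertion_point"),
                        as.integer(split_csv(m$divergent_offsets)),
                        split_csv(m$divergent_bases),
                        allele = m$allele)
  s <- build_scaffolds(ref, ins,
                       marker_spec(num("marker_offset"),
                                   m$marker_scaffold_base,
                                   m$marker_natural_base),
                       snv_spec(num("snv_wt_position"), m$snv_ref, m$snv_alt),
                       mu_name = m$mu_name)
  if (as.character(seqs[[m$mu_name]]) != s$mu$sequence)
    stop("mutant record in ", fa,
         " does not match the reconstruction from the manifest", call. = FALSE)
  s
}

## ---- synthetic CBS-analog fixture ------------------------------------------

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  force(code)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Synthetic CBS-analog reference region
#'
#' A deterministic synthetic 5000 bp sequence standing in for the CBS
#' gene region chr21:44,480,001-44,485,000 (GRCh37/hg19), with the
#' coordinate structure of the real locus: the segment 3173-3240 is the
#' duplication template, position 3184 carries the SNV reference base A
#' (the plus-strand image of c.833T>C) and position 3210 carries G, the
#' conserved base replaced by the engineered marker on the mutant
#' scaffold.  The base composition is random (fixed internal seed); only
#' the coordinates and the forced bases reproduce the real locus.
#'
#' @return A [reference_region()] named `CBS_WT` with a genomic anchor
#'   at chr21:44,480,001.
#' @export
cbs_synthetic_reference <- function() {
  seq <- with_preserved_rng({
    set.seed(833068L)
    s <- seq_chars(random_dna(5000L))
    s[3184L] <- "A"   # SNV reference base
    s[3210L] <- "G"   # natural base at the marker position
    paste(s, collapse = "")
  })
  reference_region("CBS_WT", seq, anchor_chrom = "chr21",
                   anchor_start = 44480001L)
}

divergent_default <- function(ref, offsets) {
  src <- substr(ref$sequence, 3173L, 3240L)
  copied <- seq_chars(src)[offsets]
  ## deterministic transversion, guaranteed to differ from the template
  unname(c(A = "C", C = "A", G = "T", T = "G")[copied])
}

#' The CBS-analog scaffold fixture
#'
#' Builds the synthetic scaffold pair that mirrors the CBS worked
#' example: a 68 bp duplication of wild-type positions 3173-3240
#' inserted immediately before 3173, an engineered marker at insertion
#' offset 38 (mutant-scaffold position 3210, scaffold base C vs natural
#' G), and the SNV at wild-type position 3184 (A>G).  The common allele
#' diverges from the duplication template at insertion offsets 5, 30 and
#' 60; the rare allele adds a fourth divergent base at offset 45.  The
#' divergent-offset layout is configurable so real allele sequences can
#' be substituted.
#'
#' @param allele `"common"` (3 divergent bases) or `"rare"` (4).
#' @param divergent_offsets Override the divergent-offset layout.
#' @return A `scaffold_set` with sites WT:3184, MU:3210, MU:3252.
#' @export
cbs_scaffold_set <- function(allele = c("common", "rare"),
                             divergent_offsets = NULL) {
  allele <- match.arg(allele)
  ref <- cbs_synthetic_reference()
  if (is.null(divergent_offsets))
    divergent_offsets <- if (allele == "common") c(5L, 30L, 60L)
                         else c(5L, 30L, 45L, 60L)
  ins <- insertion_spec(3173L, 3240L, 3173L,
                        divergent_offsets,
                        divergent_default(ref, divergent_offsets),
                        allele = allele)
  build_scaffolds(ref, ins, marker_spec(38L, "C"),
                  snv_spec(3184L, "A", "G"), mu_name = "CBS_MU")
}
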