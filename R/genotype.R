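ZYGOSITY_STATES <- c("ABSENT", "HET", "HOM", "NOCALL_LOWDEPTH")

#' Calling configuration
#'
#' Thresholds and filters of the pileup/zygosity/genotype stage.
#'
#' @param min_depth Minimum filtered base depth for a zygosity call
#'   (sites below it are `NOCALL_LOWDEPTH`).
#' @param margin Score margin for strict scaffold assignment: a pair is
#'   strictly mutant when its mutant-scaffold pair score exceeds the
#'   wild-type score by at least `margin` (and symmetrically).
#' @param edge_margin A counted base must lie at least this many aligned
#'   bases away from both ends of its read's aligned segment (soft-clip
#'   edges and read termini).  The default, 12, is the distance from the
#'   insertion breakpoint to the SNV: it removes the junction-adjacent
#'   bases whose placement between the duplicated copies is ambiguous.
#' @param min_base_qual Bases below this Phred quality are not counted.
#' @param frag_mean,frag_sd Fragment model for the proper-pair gate.
#' @return An object of class `call_config`.
#' @export
call_config <- function(min_depth = 15L, margin = 1L, edge_margin = 12L,
                        min_base_qual = 13L, frag_mean = 300, frag_sd = 100) {
  stopifnot(min_depth >= 1L, margin >= 1L, edge_margin >= 0L,
            min_base_qual >= 0L)
  structure(list(min_depth = as.integer(min_depth), margin = as.integer(margin),
                 edge_margin = as.integer(edge_margin),
                 min_base_qual = as.integer(min_base_qual),
                 frag_mean = frag_mean, frag_sd = frag_sd),
            class = "call_config")
}

#' Classify read pairs between the two scaffolds
#'
#' Competitive assignment from the per-scaffold pair scores: a pair is
#' `MU_STRICT` when its mutant score beats the wild-type score by at
#' least `margin` (unmapped scores count as -Inf), `WT_STRICT`
#' symmetrically, `TIE` otherwise, and `UNMAPPED` when it maps to
#' neither scaffold.  Only strictly mutant pairs carry
#' insertion-specific evidence (a junction or a divergent base).
#'
#' @param ap An [align_pairs()] result.
#' @param margin Integer score margin (default one match score).
#' @return Character vector of classes, one per pair.
#' @export
classify_pairs <- function(ap, margin = 1L) {
  sw <- ifelse(is.na(ap$wt$pair_score), -Inf, ap$wt$pair_score)
  sm <- ifelse(is.na(ap$mu$pair_score), -Inf, ap$mu$pair_score)
  out <- rep("TIE", length(sw))
  out[sm - sw >= margin] <- "MU_STRICT"
  out[sw - sm >= margin] <- "WT_STRICT"
  out[is.infinite(sw) & is.infinite(sm)] <- "UNMAPPED"
  out
}

qual_at <- function(qual, strand, qpos, read_length) {
  ## qpos is the offset in the aligned-orientation sequence; qualities
  ## are stored in sequencing orientation
  pos <- ifelse(strand == 1L, qpos + 1L, read_length - qpos)
  phred <- utf8ToInt(paste(substring(qual, pos, pos), collapse = "")) - 33L
  if (length(phred) == 0L) integer(0) else phred
}

collect_site_bases <- function(mates, quals, site, include, cfg) {
  bases <- character(0)
  bcol <- paste0("base_", site); dcol <- paste0("dist_", site)
  qcol <- paste0("qpos_", site)
  for (m in 1:2) {
    df <- mates[[m]]
    keep <- include & df$mapped & !is.na(df[[bcol]]) &
      df[[dcol]] >= cfg$edge_margin
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    rl <- nchar(quals[[m]][keep])
    ph <- qual_at(quals[[m]][keep], df$strand[keep], df[[qcol]][keep], rl)
    ok <- ph >= cfg$min_base_qual
    bases <- c(bases, df[[bcol]][keep][ok])
  }
  bases
}

#' Pile up read bases at an informative site
#'
#' Counting policy per site class:
#' * `MU_STRICT_ONLY` (mutant-scaffold sites): only strictly mutant
#'   pairs contribute, from their mutant-scaffold placements.
#' * `WT_INCLUSIVE` (the wild-type SNV site): every pair's wild-type
#'   placement contributes.
#' * `SINGLE_REFERENCE`: like `WT_INCLUSIVE`, used when only the
#'   wild-type scaffold was aligned (the reference-bias comparison
#'   mode).
#'
#' In all policies, bases under soft clips are never counted, counted
#' bases must lie at least `edge_margin` aligned bases from both ends of
#' the aligned segment, and bases below `min_base_qual` are dropped.
#'
#' @param ap An [align_pairs()] result (or, for `SINGLE_REFERENCE`, a
#'   list with element `wt`).
#' @param pairs The `read_pairs` that were aligned (for base qualities).
#' @param site Integer site position on the relevant scaffold.
#' @param policy One of `"MU_STRICT_ONLY"`, `"WT_INCLUSIVE"`,
#'   `"SINGLE_REFERENCE"`.
#' @param alt The designated alternate allele at the site.
#' @param classes Pair classes from [classify_pairs()] (not needed for
#'   `SINGLE_REFERENCE`).
#' @param cfg A [call_config()].
#' @return An object of class `pileup_counts`: list with `site`,
#'   `depth`, `counts` (named A/C/G/T) and `alt_fraction`.
#' @export
pileup_site <- function(ap, pairs, site, policy, alt, classes = NULL,
                        cfg = call_config()) {
  policy <- match.arg(policy,
                      c("MU_STRICT_ONLY", "WT_INCLUSIVE", "SINGLE_REFERENCE"))
  quals <- list(pairs$qual1, pairs$qual2)
  n <- nrow(pairs)
  if (policy == "MU_STRICT_ONLY") {
    if (is.null(classes)) stop("pair classes required", call. = FALSE)
    bases <- collect_site_bases(list(ap$mu$mate1, ap$mu$mate2), quals, site,
                                classes == "MU_STRICT", cfg)
  } else {
    bases <- collect_site_bases(list(ap$wt$mate1, ap$wt$mate2), quals, site,
                                rep(TRUE, n), cfg)
  }
  counts <- table(factor(bases, levels = DNA_BASES))
  depth <- sum(counts)
  structure(list(site = site, policy = policy, alt = alt,
                 depth = as.integer(depth),
                 counts = stats::setNames(as.integer(counts), DNA_BASES),
                 alt_fraction = if (depth > 0)
                   unname(counts[alt]) / depth else NA_real_),
            class = "pileup_counts")
}

#' @export
print.pileup_counts <- function(x, ...) {
  cat("<pileup> site ", x$site, " [", x$policy, "] depth ", x$depth,
      "  A/C/G/T = ", paste(x$counts, collapse = "/"),
      "  alt(", x$alt, ") fraction = ",
      ifelse(is.na(x$alt_fraction), "NA", sprintf("%.3f", x$alt_fraction)),
      "\n", sep = "")
  invisible(x)
}

#' Zygosity from an allele fraction
#'
#' A heterozygous call requires an alternate allele fraction in
#' \[0.20, 0.80); homozygous requires >= 0.80; below 0.20 the allele is
#' absent.  Sites with filtered depth below `min_depth` are not called.
#'
#' @param p A [pileup_site()] result, or an alternate allele fraction.
#' @param depth Depth (when `p` is a bare fraction).
#' @param min_depth Minimum depth for a call.
#' @return One of `"ABSENT"`, `"HET"`, `"HOM"`, `"NOCALL_LOWDEPTH"`.
#' @export
call_zygosity <- function(p, depth = NULL, min_depth = 15L) {
  if (inherits(p, "pileup_counts")) {
    depth <- p$depth
    frac <- p$alt_fraction
  } else {
    frac <- p
  }
  if (is.null(depth) || depth < min_depth) return("NOCALL_LOWDEPTH")
  if (frac >= 0.80) "HOM" else if (frac >= 0.20) "HET" else "ABSENT"
}

new_call <- function(genotype, sig, reason = NA_character_,
                     zygosity = NA_character_, mode = "dual_scaffold") {
  structure(list(genotype = genotype, zygosity = zygosity, reason = reason,
                 signature = sig, mode = mode),
            class = "genotype_call")
}

#' Resolve genotype and phase from a site signature
#'
#' The decision table over the zygosity triple at (WT SNV site, MU
#' marker site, MU cis-SNV site).  The insertion is present iff the
#' marker is homozygous among strictly mutant pairs at adequate depth
#' (all such pairs carry the insertion, so a genuine insertion --
#' heterozygous or homozygous -- always reads HOM there; a HET marker is
#' anomalous and yields no call).  Given insertion presence, the
#' remaining two states identify the row: complex (cis) carriers light
#' up the cis site, trans configurations additionally (or instead)
#' light up the wild-type SNV site as HET.  Insertion zygosity is
#' deliberately not resolved: heterozygous and homozygous carriers of
#' the same allele configuration share a signature.  Signatures outside
#' the table yield `NO_CALL`.
#'
#' @param states Named character vector with elements `wt_snv`,
#'   `mu_marker`, `mu_cis_snv`, each a zygosity state.
#' @return An object of class `genotype_call` (fields `genotype`,
#'   `zygosity` sub-label for the SNV-only class, `reason` for
#'   `NO_CALL`).
#' @export
resolve_genotype <- function(states) {
  stopifnot(all(c("wt_snv", "mu_marker", "mu_cis_snv") %in% names(states)),
            all(states %in% ZYGOSITY_STATES))
  wt <- states[["wt_snv"]]
  mk <- states[["mu_marker"]]
  cis <- states[["mu_cis_snv"]]
  if (mk == "HET")
    return(new_call("NO_CALL", states, reason = "anomalous_marker"))
  if (mk != "HOM") {
    ## no insertion evidence: the mutant-only sites must be quiet
    if (cis %in% c("HET", "HOM"))
      return(new_call("NO_CALL", states, reason = "inconsistent_signature"))
    if (wt == "NOCALL_LOWDEPTH")
      return(new_call("NO_CALL", states, reason = "low_depth"))
    if (wt == "HET") return(new_call("SNV", states, zygosity = "HET"))
    if (wt == "HOM") return(new_call("SNV", states, zygosity = "HOM"))
    return(new_call("WT", states))
  }
  ## insertion present
  if (wt == "NOCALL_LOWDEPTH" || cis == "NOCALL_LOWDEPTH")
    return(new_call("NO_CALL", states, reason = "low_depth"))
  if (wt == "ABSENT" && cis == "ABSENT") return(new_call("INS", states))
  if (wt == "ABSENT" && cis == "HOM") return(new_call("COMPLEX", states))
  if (wt == "ABSENT" && cis == "HET")
    return(new_call("INS_TRANS_COMPLEX", states))
  if (wt == "HET" && cis == "ABSENT")
    return(new_call("SNV_TRANS_INS", states))
  if (wt == "HET" && cis == "HOM")
    return(new_call("SNV_TRANS_COMPLEX", states))
  new_call("NO_CALL", states, reason = "inconsistent_signature")
}

genotype_description <- function(call) {
  switch(call$genotype,
    WT = "wild-type at both variant positions",
    SNV = paste0("SNV only (", call$zygosity, "); no insertion"),
    INS = "insertion only (zygosity undetermined); no SNV",
    COMPLEX = paste("complex variant (SNV in cis with the insertion)",
                    "present; insertion zygosity undetermined"),
    SNV_TRANS_INS = "SNV in trans with the insertion",
    SNV_TRANS_COMPLEX = "SNV in trans with the complex variant",
    INS_TRANS_COMPLEX = "insertion in trans with the complex variant",
    NO_CALL = paste0("no call (", call$reason, ")"))
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("<genotype_call> [", x$mode, "]\n", sep = "")
  cat("  genotype:", x$genotype,
      if (!is.na(x$zygosity)) paste0("(", x$zygosity, ")"), "\n")
  cat("  ", genotype_description(x), "\n", sep = "")
  if (!is.null(x$sites)) {
    cat("  sites:\n")
    print(x$sites, row.names = FALSE)
  } else {
    cat("  signature:", paste(names(x$signature), x$signature, sep = "=",
                              collapse = "  "), "\n")
  }
  invisible(x)
}

as_pairs_input <- function(input) {
  if (inherits(input, "read_pairs") || is.data.frame(input)) return(input)
  if (is.character(input) && length(input) == 2L)
    return(read_fastq_pairs(input[1], input[2]))
  stop("input must be a read_pairs object or paths to two FASTQ files",
       call. = FALSE)
}

site_row <- function(name, scaffold, pos, pu, state) {
  data.frame(site = name, scaffold = scaffold, position = pos,
             depth = pu$depth,
             alt_fraction = round(ifelse(is.na(pu$alt_fraction), NA,
                                         pu$alt_fraction), 4),
             state = state, stringsAsFactors = FALSE)
}

#' End-to-end dual-scaffold genotype call
#'
#' Aligns every read pair to both scaffolds, classifies pairs
#' competitively, piles up the three informative sites under the
#' dual-scaffold policy, calls per-site zygosity and resolves the
#' genotype/phase through the decision table.  Deterministic given the
#' input reads.
#'
#' @param input A `read_pairs` object or character vector of two FASTQ
#'   paths (mate 1, mate 2).
#' @param sset A `scaffold_set`.
#' @param scheme A [scoring_scheme()].
#' @param cfg A [call_config()].
#' @return A `genotype_call` with a `sites` report table (per-site
#'   depth, alternate allele fraction and state), the pair-class table
#'   and the signature.
#' @export
call_sample <- function(input, sset, scheme = scoring_scheme(),
                        cfg = call_config()) {
  pairs <- as_pairs_input(input)
  if (nrow(pairs) == 0L) {
    states <- c(wt_snv = "NOCALL_LOWDEPTH", mu_marker = "NOCALL_LOWDEPTH",
                mu_cis_snv = "NOCALL_LOWDEPTH")
    call <- new_call("NO_CALL", states, reason = "low_depth")
    call$sites <- data.frame()
    call$n_pairs <- 0L
    return(call)
  }
  ap <- align_pairs(pairs, sset, scheme, cfg$frag_mean, cfg$frag_sd)
  classes <- classify_pairs(ap, cfg$margin)
  alt <- sset$snv$alt_base
  pu_wt <- pileup_site(ap, pairs, sset$sites$wt_snv, "WT_INCLUSIVE", alt,
                       classes, cfg)
  pu_mk <- pileup_site(ap, pairs, sset$sites$mu_marker, "MU_STRICT_ONLY",
                       sset$marker$natural_base, classes, cfg)
  pu_cis <- pileup_site(ap, pairs, sset$sites$mu_cis_snv, "MU_STRICT_ONLY",
                        alt, classes, cfg)
  states <- c(wt_snv = call_zygosity(pu_wt, min_depth = cfg$min_depth),
              mu_marker = call_zygosity(pu_mk, min_depth = cfg$min_depth),
              mu_cis_snv = call_zygosity(pu_cis, min_depth = cfg$min_depth))
  call <- resolve_genotype(states)
  call$sites <- rbind(
    site_row("wt_snv", sset$wt$name, sset$sites$wt_snv, pu_wt,
             states[["wt_snv"]]),
    site_row("mu_marker", sset$mu$name, sset$sites$mu_marker, pu_mk,
             states[["mu_marker"]]),
    site_row("mu_cis_snv", sset$mu$name, sset$sites$mu_cis_snv, pu_cis,
             states[["mu_cis_snv"]]))
  call$pair_classes <- table(factor(classes, levels = c("WT_STRICT",
                                                        "MU_STRICT", "TIE",
                                                        "UNMAPPED")))
  call$pileups <- list(wt_snv = pu_wt, mu_marker = pu_mk, mu_cis_snv = pu_cis)
  call$n_pairs <- nrow(pairs)
  call
}

#' Single-reference comparison call
#'
#' Aligns reads to the wild-type scaffold only and reports the naive
#' pileup and zygosity at the SNV site -- the comparison mode that
#' demonstrates reference bias: reads from insertion-bearing haplotypes
#' soft-clip onto the single reference and the variant allele fraction
#' of cis (complex) carriers is suppressed below the calling thresholds.
#'
#' @inheritParams call_sample
#' @return A `genotype_call` (mode `single_reference`) whose genotype is
#'   the naive SNV zygosity readout; includes the site pileup.
#' @export
call_single_reference <- function(input, sset, scheme = scoring_scheme(),
                                  cfg = call_config()) {
  pairs <- as_pairs_input(input)
  site <- sset$sites$wt_snv
  alt <- sset$snv$alt_base
  if (nrow(pairs) == 0L) {
    pu <- structure(list(site = site, policy = "SINGLE_REFERENCE", alt = alt,
                         depth = 0L,
                         counts = stats::setNames(integer(4), DNA_BASES),
                         alt_fraction = NA_real_), class = "pileup_counts")
  } else {
    band <- default_band(sset$insertion$length)
    m1 <- align_reads(pairs$seq1, sset$wt, scheme, site, band = band)
    m2 <- align_reads(pairs$seq2, sset$wt, scheme, site, band = band)
    ap <- list(wt = list(mate1 = m1, mate2 = m2))
    pu <- pileup_site(ap, pairs, site, "SINGLE_REFERENCE", alt, cfg = cfg)
  }
  state <- call_zygosity(pu, min_depth = cfg$min_depth)
  genotype <- switch(state, HET = "SNV", HOM = "SNV",
                     ABSENT = "WT", NOCALL_LOWDEPTH = "NO_CALL")
  call <- new_call(genotype, c(wt_snv = state),
                   reason = if (genotype == "NO_CALL") "low_depth"
                            else NA_character_,
                   zygosity = if (genotype == "SNV") state else NA_character_,
                   mode = "single_reference")
  call$sites <- site_row("wt_snv", sset$wt$name, site, pu, state)
  call$pileups <- list(wt_snv = pu)
  call$n_pairs <- nrow(pairs)
  call
}

#' Write a structured call report
#'
#' Key/value + table plain-text report of a [call_sample()] result.
#'
#' @param call A `genotype_call`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_call_report <- function(call, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("mode\t", call$mode),
               paste0("genotype\t", call$genotype),
               paste0("zygosity\t", ifelse(is.na(call$zygosity), ".",
                                           call$zygosity)),
               paste0("interpretation\t", genotype_description(call)),
               paste0("n_pairs\t", call$n_pairs),
               paste0("signature\t",
                      paste(names(call$signature), call$signature,
                            sep = "=", collapse = ";"))), con)
  if (!is.null(call$sites) && nrow(call$sites)) {
    writeLines("", con)
    write.table(call$sites, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
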