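sam_flag <- function(mate, strand, mstrand, mapped, mmapped, proper) {
  f <- 1L + if (mate == 1L) 64L else 128L
  f + (!mapped) * 4L + (!mmapped) * 8L +
    (mapped & strand == -1L) * 16L + (mmapped & mstrand == -1L) * 32L +
    (proper & mapped & mmapped) * 2L
}

#' Export alignments as SAM, one file per scaffold
#'
#' Aligns the pairs to both scaffolds and writes
#' `<out_dir>/<scaffold>.sam` for each, with `@SQ` headers taken from
#' the scaffold set, 1-based positions, and CIGAR strings using M/I/D/S
#' operations (soft clips as `S`).  MAPQ is 60 for pairs assigned
#' strictly to one scaffold and 0 for cross-scaffold ties.
#'
#' @param pairs A `read_pairs` object.
#' @param sset A `scaffold_set`.
#' @param out_dir Output directory.
#' @param scheme A [scoring_scheme()].
#' @param cfg A [call_config()] (fragment model and margin).
#' @return Invisibly, the paths written.
#' @export
write_sam <- function(pairs, sset, out_dir, scheme = scoring_scheme(),
                      cfg = call_config()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  ap <- align_pairs(pairs, sset, scheme, cfg$frag_mean, cfg$frag_sd)
  classes <- classify_pairs(ap, cfg$margin)
  paths <- character(0)
  for (sc in c("wt", "mu")) {
    region <- sset[[sc]]
    a <- ap[[sc]]
    mapq <- ifelse(classes == "TIE", 0L, 60L)
    path <- file.path(out_dir, paste0(region$name, ".sam"))
    con <- file(path, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@SQ\tSN:", region$name, "\tLN:",
                        nchar(region$sequence)),
                 "@PG\tID:scafphase\tPN:scafphase"), con)
    for (m in 1:2) {
      df <- a[[paste0("mate", m)]]
      mt <- a[[paste0("mate", 3L - m)]]
      seqs <- pairs[[paste0("seq", m)]]
      quals <- pairs[[paste0("qual", m)]]
      rc <- df$mapped & df$strand == -1L
      rc[is.na(rc)] <- FALSE
      seqs[rc] <- revcomp(seqs[rc])
      quals[rc] <- vapply(quals[rc], function(q)
        intToUtf8(rev(utf8ToInt(q))), character(1))
      flags <- mapply(sam_flag, m, df$strand, mt$strand, df$mapped,
                      mt$mapped, a$proper)
      lines <- paste(pairs$id, flags, region$name,
                     ifelse(df$mapped, df$start, 0L),
                     ifelse(df$mapped, mapq, 0L),
                     ifelse(df$mapped, df$cigar, "*"), "=",
                     ifelse(mt$mapped, mt$start, 0L), 0L, seqs, quals,
                     sep = "\t")
      writeLines(lines, con)
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
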