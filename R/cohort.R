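round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Carrier rate as a percentage
#'
#' `100 * k / n`, reported with 2-decimal half-up rounding (the
#' convention of the printed cohort tables).
#'
#' @param k Number of carriers (0 <= k <= n).
#' @param n Cohort size (> 0).
#' @param digits Decimal places.
#' @return Numeric percentage(s).
#' @examples
#' carrier_rate(11153, 60318)  # 18.49
#' @export
carrier_rate <- function(k, n, digits = 2L) {
  if (any(n <= 0)) stop("cohort size must be positive", call. = FALSE)
  if (any(k < 0 | k > n)) stop("carrier count outside [0, n]", call. = FALSE)
  round_half_up(100 * k / n, digits)
}

#' Build a carriers-vs-non-carriers contingency table
#'
#' @param k_a,n_a Carriers and total in cohort A.
#' @param k_b,n_b Carriers and total in cohort B.
#' @return A 2x2 integer matrix (rows = cohorts, columns =
#'   carrier / non-carrier).
#' @export
carriers_table <- function(k_a, n_a, k_b, n_b) {
  m <- matrix(as.integer(c(k_a, n_a - k_a, k_b, n_b - k_b)), nrow = 2,
              byrow = TRUE,
              dimnames = list(c("cohort_a", "cohort_b"),
                              c("carrier", "non_carrier")))
  if (any(m < 0)) stop("negative cell count", call. = FALSE)
  m
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value with the sum-of-smaller-probabilities
#' convention: all tables with the observed margins whose hypergeometric
#' probability does not exceed that of the observed table (within
#' relative tolerance 1e-7) contribute.  A table with a zero margin
#' carries no contrast and is assigned p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts (e.g. from
#'   [carriers_table()]).
#' @return The p-value in \[0, 1\].
#' @examples
#' fisher_exact_two_sided(carriers_table(22, 7718, 2, 518))  # ~0.66
#' @export
fisher_exact_two_sided <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  stats::fisher.test(tab)$p.value
}

#' Packaged cohort carrier counts
#'
#' The per-population carrier counts of the clinical-cohort comparison
#' (current study vs gnomAD) for the SNV and the complex variant, stored
#' verbatim as printed: totals, positive-sample counts `(n)`, the
#' printed rates and p-values.  Four printed rates are internally
#' inconsistent with their own counts; these rows are annotated in the
#' `note` column and the counts are taken as authoritative.
#'
#' @return A data.frame with one row per population x variant.
#' @export
cbs_cohort_counts <- function() {
  path <- system.file("extdata", "cbs_cohort_counts.tsv",
                      package = "scafphase", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", quote = "", fill = TRUE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Reconstruct the cohort comparison table
#'
#' Computes carrier rates and two-sided Fisher's exact p-values for
#' every population x variant row of a counts table, flagging
#' significance at `alpha`.
#'
#' @param counts A data.frame with columns `population`, `variant`,
#'   `gnomad_total`, `gnomad_n`, `current_total`, `current_n`
#'   (defaults to the packaged fixture [cbs_cohort_counts()]).
#' @param alpha Significance level.
#' @return A data.frame with rates (`rate_gnomad`, `rate_current`, %),
#'   `p_value`, and `significant`; rows with missing counts are skipped
#'   with a warning.
#' @export
compare_cohorts <- function(counts = cbs_cohort_counts(), alpha = 0.05) {
  need <- c("population", "variant", "gnomad_total", "gnomad_n",
            "current_total", "current_n")
  stopifnot(all(need %in% names(counts)))
  cnt <- counts[need]
  complete <- stats::complete.cases(cnt)
  if (any(!complete)) {
    warning(sum(!complete), " row(s) skipped for missing counts")
    cnt <- cnt[complete, , drop = FALSE]
  }
  p <- mapply(function(ka, na, kb, nb)
    fisher_exact_two_sided(carriers_table(ka, na, kb, nb)),
    cnt$gnomad_n, cnt$gnomad_total, cnt$current_n, cnt$current_total)
  data.frame(
    population = cnt$population, variant = cnt$variant,
    gnomad_total = cnt$gnomad_total, gnomad_n = cnt$gnomad_n,
    current_total = cnt$current_total, current_n = cnt$current_n,
    rate_gnomad = carrier_rate(cnt$gnomad_n, cnt$gnomad_total),
    rate_current = carrier_rate(cnt$current_n, cnt$current_total),
    p_value = p, significant = p < alpha,
    stringsAsFactors = FALSE)
}
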