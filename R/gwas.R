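#' GWAS of SNP dosages on predicted random slopes
#'
#' For one probe, regresses the per-individual predicted (BLUP) random
#' slope on each SNP's dosage by simple linear regression and reports the
#' additive effect, its standard error and the two-sided t-test p-value.
#' SNPs with zero dosage variance on the overlapping individuals are
#' skipped. No covariates enter the regression: the slopes are already
#' residualized for covariates upstream.
#'
#' @param slopes Tibble with columns `individual_id` and `slope` (one
#'   probe's BLUP slopes), e.g. from [predict_blups()].
#' @param geno A `genotype_matrix` whose dosage columns are named by
#'   individual id.
#' @param probe_id,probe_chrom,probe_pos Optional probe identity carried
#'   into the result (needed for cis/trans classification).
#' @return A tibble of class `slope_assoc`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `statistic`, `p`, `n` (+ probe columns when supplied).
#' @export
gwas_slope <- function(slopes, geno, probe_id = NULL, probe_chrom = NULL,
                       probe_pos = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  .assert(all(c("individual_id", "slope") %in% names(slopes)),
          "slopes needs columns individual_id and slope")
  common <- intersect(slopes$individual_id, colnames(geno$dosage))
  .assert(length(common) >= 3L, "need at least 3 overlapping individuals")
  b <- slopes$slope[match(common, slopes$individual_id)]
  D <- geno$dosage[, common, drop = FALSE]

  res <- purrr::map(seq_len(nrow(D)), function(k) {
    d <- D[k, ]
    ok <- !is.na(d)
    n <- sum(ok)
    if (n < 3L || var(d[ok]) == 0) return(NULL)  # monomorphic / too few: skip
    dv <- d[ok] - mean(d[ok]); bv <- b[ok] - mean(b[ok])
    sxx <- sum(dv^2)
    beta <- sum(dv * bv) / sxx
    rss <- sum((bv - beta * dv)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    stat <- beta / se
    tibble::tibble(snp_id = geno$info$snp_id[k],
                   chrom = geno$info$chrom[k], pos = geno$info$pos[k],
                   beta = beta, se = se, statistic = stat,
                   p = 2 * stats::pt(-abs(stat), df = n - 2), n = n)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0)
    inform(sprintf("%d SNP(s) skipped (zero dosage variance or < 3 individuals)",
                   skipped))
  out <- dplyr::bind_rows(res)
  if (!is.null(probe_id)) {
    out$probe_id <- probe_id
    out$probe_chrom <- probe_chrom %||% NA
    out$probe_pos <- probe_pos %||% NA
    if (!is.null(probe_chrom)) out <- classify_cis_trans(out)
  }
  class(out) <- c("slope_assoc", class(out))
  out
}

#' Squared-correlation linkage disequilibrium between two SNPs
#'
#' @param geno A `genotype_matrix`.
#' @param snp1,snp2 SNP ids present in `geno`.
#' @return Squared Pearson correlation of the dosages over individuals
#'   non-missing for both SNPs; symmetric, in \[0, 1\].
#' @export
ld_r2 <- function(geno, snp1, snp2) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  i <- match(c(snp1, snp2), geno$info$snp_id)
  .assert(!anyNA(i), "both SNPs must be present in geno")
  x <- geno$dosage[i[1], ]; y <- geno$dosage[i[2], ]
  ok <- !is.na(x) & !is.na(y)
  .assert(sd(x[ok]) > 0 && sd(y[ok]) > 0,
          "zero dosage variance on shared individuals")
  cor(x[ok], y[ok])^2
}

#' Greedy LD clumping of association results
#'
#' Restricted to SNPs passing `p_threshold`, repeatedly takes the
#' remaining SNP with the smallest p-value (ties broken by `snp_id`) as an
#' index SNP and absorbs into its clump every remaining significant SNP on
#' the same chromosome within `window` bp whose dosage r-squared with the
#' index exceeds `r2_threshold` (strictly; r2 equal to the threshold is
#' kept independent). Output is invariant to the input row order.
#'
#' @param assoc Association tibble for one probe (see [gwas_slope()]).
#' @param geno The `genotype_matrix` used as LD reference.
#' @param r2_threshold Clumping r-squared threshold (default 0.1).
#' @param window Positional window in bp (default 1 Mb).
#' @param p_threshold Significance threshold (default 5e-8).
#' @return A list of class `clump_report`: `index` (tibble of retained
#'   index SNPs) and `members` (tibble `index_snp`, `snp_id`, `r2`).
#' @export
clump <- function(assoc, geno, r2_threshold = 0.1, window = 1e6,
                  p_threshold = 5e-8) {
  .assert(all(c("snp_id", "chrom", "pos", "p") %in% names(assoc)),
          "assoc needs snp_id, chrom, pos, p")
  sig <- assoc |>
    dplyr::filter(.data$p < p_threshold) |>
    dplyr::arrange(.data$p, .data$snp_id)
  index <- sig[0, ]
  members <- tibble::tibble(index_snp = character(), snp_id = character(),
                            r2 = numeric())
  while (nrow(sig) > 0) {
    top <- sig[1, ]
    index <- dplyr::bind_rows(index, top)
    rest <- sig[-1, ]
    if (nrow(rest) > 0) {
      near <- rest$chrom == top$chrom & abs(rest$pos - top$pos) <= window
      r2 <- rep(NA_real_, nrow(rest))
      r2[near] <- vapply(rest$snp_id[near], function(s)
        ld_r2(geno, top$snp_id, s), numeric(1))
      absorb <- near & r2 > r2_threshold
      absorb[is.na(absorb)] <- FALSE
      if (any(absorb))
        members <- dplyr::bind_rows(members, tibble::tibble(
          index_snp = top$snp_id, snp_id = rest$snp_id[absorb],
          r2 = r2[absorb]))
      sig <- rest[!absorb, ]
    } else sig <- rest
  }
  structure(list(index = index, members = members), class = "clump_report")
}

#' @export
print.clump_report <- function(x, ...) {
  cat(sprintf("clump_report: %d index SNP(s), %d absorbed member(s)\n",
              nrow(x$index), nrow(x$members)))
  print(x$index)
  invisible(x)
}

#' Classify SNP-probe pairs as cis or trans
#'
#' A pair is cis when the SNP and probe share a chromosome, trans
#' otherwise; distance plays no role.
#'
#' @param assoc Tibble with columns `chrom` and `probe_chrom`.
#' @return `assoc` with an added/updated `cis_trans` column.
#' @export
classify_cis_trans <- function(assoc) {
  .assert(all(c("chrom", "probe_chrom") %in% names(assoc)),
          "assoc needs chrom and probe_chrom")
  .assert(!anyNA(assoc$chrom) && !anyNA(assoc$probe_chrom),
          "missing chromosome values")
  dplyr::mutate(assoc, cis_trans = ifelse(.data$chrom == .data$probe_chrom,
                                          "cis", "trans"))
}
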