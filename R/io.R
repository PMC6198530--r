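# TSV/BED/VCF interfaces. Numeric columns are written with 17 significant
# digits so a written file re-reads to bit-identical doubles.

#' @noRd
.write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the standard file schemas: `meth.tsv` (probe_id + one column per
#' sample, M-values), `samples.tsv` (sample sheet), `probes.tsv` (probe
#' manifest), `genotypes.tsv` (snp_id/chrom/pos/a1/a2 + dosage columns),
#' `annotations.bed` (0-based half-open, class in column 4), and the truth
#' tables `truth_probes.tsv` / `truth_snp_effects.tsv`.
#'
#' @param cohort A `meth_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "meth_cohort"), "cohort must be a meth_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth_df <- tibble::as_tibble(cohort$meth, rownames = "probe_id")
  .write_tsv(meth_df, file.path(dir, "meth.tsv"))
  .write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  .write_tsv(cohort$probes, file.path(dir, "probes.tsv"))
  if (!is.null(cohort$genotypes)) {
    g <- cohort$genotypes
    gd <- dplyr::bind_cols(g$info,
                           tibble::as_tibble(g$dosage, .name_repair = "minimal"))
    .write_tsv(gd, file.path(dir, "genotypes.tsv"))
  }
  bed <- cohort$annotations
  write.table(
    data.frame(chrom = paste0("chr", bed$chrom), start = bed$start,
               end = bed$end, name = bed$class),
    file.path(dir, "annotations.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_tsv(cohort$truth$probe_params, file.path(dir, "truth_probes.tsv"))
  .write_tsv(cohort$truth$snp_effects, file.path(dir, "truth_snp_effects.tsv"))
  invisible(dir)
}

#' Read a methylation matrix TSV
#'
#' First column `probe_id`, remaining columns one per sample. If
#' `beta = TRUE` the values are beta-values and are converted to M-values
#' with [beta_to_m()].
#'
#' @param path TSV file path.
#' @param beta Are the stored values beta-values?
#' @return A probes x samples numeric matrix.
#' @export
read_meth_matrix <- function(path, beta = FALSE) {
  df <- read.delim(path, check.names = FALSE)
  .assert(names(df)[1] == "probe_id", "first column must be probe_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  if (beta) m[] <- beta_to_m(m)
  m
}

#' Read a sample sheet TSV
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- tibble::as_tibble(read.delim(path, check.names = FALSE))
  .assert(all(c("sample_id", "individual_id", "wave", "age_years") %in%
                names(df)),
          "sample sheet needs sample_id, individual_id, wave, age_years")
  .assert(!any(duplicated(df[c("individual_id", "wave")])),
          "(individual_id, wave) must be unique")
  df
}

#' Read SNP dosages from a dosage TSV
#'
#' Columns `snp_id`, `chrom`, `pos`, `a1`, `a2` followed by one dosage
#' column per individual.
#'
#' @param path TSV file path.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- c("snp_id", "chrom", "pos", "a1", "a2")
  .assert(all(meta %in% names(df)), "dosage TSV needs snp_id/chrom/pos/a1/a2")
  extra <- intersect(names(df), c(meta, "maf"))
  d <- as.matrix(df[, setdiff(names(df), extra), drop = FALSE])
  rownames(d) <- df$snp_id
  structure(list(info = tibble::as_tibble(df[extra]), dosage = d),
            class = "genotype_matrix")
}

#' Read SNP dosages from a VCF with a DS FORMAT field
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  .assert(requireNamespace("vcfR", quietly = TRUE),
          "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  info <- tibble::tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    a1 = fix$REF, a2 = fix$ALT)
  rownames(ds) <- info$snp_id
  structure(list(info = info, dosage = ds), class = "genotype_matrix")
}

#' Read an annotation track from a BED file
#'
#' Standard 4-column BED: 0-based half-open intervals with the class name
#' in the fourth column. A leading "chr" prefix is stripped from numeric
#' chromosome names.
#'
#' @param path BED file path.
#' @return A tibble `chrom`, `start`, `end`, `class`.
#' @export
read_bed_track <- function(path) {
  .assert(requireNamespace("rtracklayer", quietly = TRUE),
          "reading BED requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- sub("^chr", "", as.character(GenomeInfoDb::seqnames(gr)))
  suppressWarnings({
    num <- as.integer(chrom)
  })
  tibble::tibble(
    chrom = if (!anyNA(num)) num else chrom,
    start = BiocGenerics::start(gr) - 1L,     # back to 0-based
    end = BiocGenerics::end(gr),
    class = gr$name)
}

#' Pivot a methylation matrix and sample sheet into scan-ready long format
#'
#' Convenience for data that needs no residualization (e.g. already
#' preprocessed matrices): joins the sample sheet, standardizes age over
#' all samples and returns the long tibble [scan_probes()] expects.
#'
#' @param meth Probes x samples matrix.
#' @param samples Sample sheet tibble.
#' @return A tibble `probe_id`, `sample_id`, `individual_id`, `age_years`,
#'   `t`, `y`.
#' @export
meth_long <- function(meth, samples) {
  .assert(all(colnames(meth) %in% samples$sample_id),
          "every meth column needs a sample sheet row")
  samples <- samples[match(colnames(meth), samples$sample_id), ]
  t_std <- standardize_age(samples$age_years)
  tibble::tibble(
    probe_id = rep(rownames(meth), ncol(meth)),
    sample_id = rep(samples$sample_id, each = nrow(meth)),
    individual_id = rep(samples$individual_id, each = nrow(meth)),
    age_years = rep(samples$age_years, each = nrow(meth)),
    t = rep(t_std, each = nrow(meth)),
    y = as.vector(meth))
}
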