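# Readers and writers for the pipeline's tabular formats. All tabular output
# is tab-delimited with documented headers; floats are serialized at 12
# significant digits.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write a dosage matrix as tab-delimited text
#'
#' Header: `snp_id, chrom, pos, a1, a2`, then one column per subject; one row
#' per SNP.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- t(genotypes$dosage)
  tab <- cbind(genotypes$snps[, c("snp_id", "chrom", "pos", "a1", "a2")],
               as.data.frame(d))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from disk
#'
#' Supports the package's tab-delimited dosage format and VCF. For VCF, the
#' per-sample `DS` (imputed dosage) field is preferred when present;
#' otherwise `GT` hard calls are summed to a dosage. Positions are 1-based
#' and the region filter is a closed interval.
#'
#' @param path File path.
#' @param format `"dosage_tsv"` or `"vcf"` (guessed from the extension by
#'   default).
#' @param region Optional region filter (see [parse_region()]).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "dosage_tsv", "vcf"),
                           region = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  gm <- if (format == "vcf") .read_vcf_genotypes(path) else
    .read_dosage_tsv(path)
  if (!is.null(region)) {
    region <- parse_region(region)
    sel <- gm$snps$chrom == region$chrom & gm$snps$pos >= region$start &
      gm$snps$pos <= region$end
    if (!any(sel)) stop("no SNPs in region after filtering")
    gm$snps <- gm$snps[sel, , drop = FALSE]
    gm$dosage <- gm$dosage[, sel, drop = FALSE]
  }
  gm
}

.read_dosage_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed dosage file ", path, ": ",
                             conditionMessage(e)))
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(tab)))
    stop("dosage file must start with columns ", paste(need, collapse = ", "))
  subj <- setdiff(names(tab), need)
  if (length(subj) == 0) stop("dosage file has no subject columns")
  dosage <- t(as.matrix(tab[, subj, drop = FALSE]))
  if (!is.numeric(dosage)) {
    bad <- which(!vapply(tab[, subj, drop = FALSE], is.numeric, logical(1)))[1]
    stop("non-numeric dosage in column '", subj[bad], "' (data line ",
         which(is.na(suppressWarnings(as.numeric(tab[[subj[bad]]]))))[1], ")")
  }
  colnames(dosage) <- tab$snp_id
  snps <- tab[, need]
  snps$chrom <- as.character(snps$chrom)
  snps$raf <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

.read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]))
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@gt))
  }
  dosage <- t(ds)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) | ids == "."))
  colnames(dosage) <- ids
  snps <- data.frame(snp_id = ids, chrom = sub("^chr", "", fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]), a1 = fix[, "ALT"],
                     a2 = fix[, "REF"],
                     raf = colMeans(dosage, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' Write long-format phenotypes and subject covariates
#'
#' Phenotypes go to `<stem>_long.csv` (`subject_id, age_years, sph_equiv_D`)
#' and covariates to `<stem>_covar.csv` (`subject_id, sex, genotype,
#' reading`, plus any extra columns present).
#'
#' @param x A `long_phenotypes` or `synthetic_cohort`, or a list with
#'   `phenotypes` and `covariates` data frames.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_phenotypes <- function(x, stem) {
  ph <- x$phenotypes; cv <- x$covariates
  ph$age_years <- .fmt_num(ph$age_years)
  ph$sph_equiv_D <- .fmt_num(ph$sph_equiv_D)
  p1 <- paste0(stem, "_long.csv"); p2 <- paste0(stem, "_covar.csv")
  utils::write.csv(ph, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(cv, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Read long-format phenotypes and covariates
#'
#' @param long_path CSV with `subject_id, age_years, sph_equiv_D`.
#' @param covar_path CSV with `subject_id` plus covariate columns.
#' @return List with `phenotypes` and `covariates` data frames.
#' @export
read_phenotypes <- function(long_path, covar_path) {
  ph <- utils::read.csv(long_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "sph_equiv_D")
  if (!all(need %in% names(ph)))
    stop("long phenotype file must have columns ", paste(need, collapse = ", "))
  cv <- utils::read.csv(covar_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(cv))
    stop("covariate file must have a subject_id column")
  list(phenotypes = ph, covariates = cv)
}

#' Write a region scan as a summary-statistics table
#'
#' Tab-delimited columns: `snp_id, chrom, pos, a1, a2, af, beta, se, t, p,
#' n`.
#'
#' @param scan A `region_scan`.
#' @param genotypes The `genotype_matrix` the scan was run on (for alleles
#'   and frequencies).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(scan, genotypes, path) {
  stopifnot(inherits(scan, "region_scan"))
  r <- scan$results
  ix <- match(r$snp_id, genotypes$snps$snp_id)
  af <- colMeans(genotypes$dosage, na.rm = TRUE)[ix] / 2
  tab <- data.frame(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
                    a1 = genotypes$snps$a1[ix], a2 = genotypes$snps$a2[ix],
                    af = .fmt_num(af), beta = .fmt_num(r$beta),
                    se = .fmt_num(r$se), t = .fmt_num(r$statistic),
                    p = .fmt_num(r$p), n = r$n, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics table
#'
#' Accepts the format written by [write_summary_stats()] or any tab-delimited
#' table with at least `pos` and `p` columns (`snp_id` and `chrom` used when
#' present).
#'
#' @param path File path.
#' @return `data.frame` of summary statistics.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "p") %in% names(tab)))
    stop("summary-statistics table needs at least 'pos' and 'p' columns")
  tab
}
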