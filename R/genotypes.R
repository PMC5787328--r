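#' Genotype container
#'
#' Builds a `geno_matrix`: an individuals-by-SNP matrix of allele counts
#' (0/1/2 of the counted allele, `NA` for missing) together with identifier
#' vectors and per-SNP frequencies of the counted allele computed from the
#' non-missing calls.
#'
#' @param counts integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param ind_ids,snp_ids identifiers; default to row/column names or
#'   generated labels.
#' @return An object of class `geno_matrix` with elements `counts`,
#'   `ind_ids`, `snp_ids` and `freqs`.
#' @export
geno_matrix <- function(counts, ind_ids = rownames(counts),
                        snp_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("genotype counts must be 0, 1, 2 or NA; found ", counts[bad][1L],
         " at individual ", idx[1L], ", SNP ", idx[2L])
  }
  if (is.null(ind_ids)) ind_ids <- paste0("ind", seq_len(nrow(counts)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(counts)))
  dimnames(counts) <- list(ind_ids, snp_ids)
  structure(list(counts = counts,
                 ind_ids = as.character(ind_ids),
                 snp_ids = as.character(snp_ids),
                 freqs = .geno_freqs(counts)),
            class = "geno_matrix")
}

.geno_freqs <- function(counts) {
  nonmiss <- colSums(!is.na(counts))
  if (any(nonmiss == 0))
    stop("SNP(s) with no non-missing calls: ",
         paste(head(colnames(counts)[nonmiss == 0], 5), collapse = ", "))
  colSums(counts, na.rm = TRUE) / (2 * nonmiss)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$ind_ids), "individuals x",
      length(x$snp_ids), "SNPs\n")
  nmiss <- sum(is.na(x$counts))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)", 100 * nmiss / length(x$counts)), "\n")
  cat("  counted-allele frequency: ",
      sprintf("%.3f-%.3f (median %.3f)", min(x$freqs), max(x$freqs),
              stats::median(x$freqs)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$counts)

#' Read genotypes from a TSV or PLINK .raw file
#'
#' The TSV dialect has a header `id<TAB>snp1<TAB>...` and one row per
#' individual with counts 0/1/2 and missing code `NA`.  The PLINK `.raw`
#' dialect is whitespace-delimited with columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one count column per SNP.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ""
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf)) != 1L)
    stop("malformed genotype file ", path, ": line ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L])
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
  if (dialect == "tsv") {
    ids <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L, drop = FALSE])
  } else {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) <= 6L || !identical(toupper(names(tab)[1:6]), meta))
      stop("not a PLINK .raw file: expected header columns ",
           paste(meta, collapse = " "))
    ids <- as.character(tab[["IID"]])
    counts <- as.matrix(tab[, -(1:6), drop = FALSE])
  }
  if (anyDuplicated(ids)) stop("duplicated individual ids in ", path)
  rownames(counts) <- ids
  geno_matrix(counts, ind_ids = ids)
}

#' Write genotypes in a dialect readable by [read_genotypes()]
#'
#' @param G a [geno_matrix()].
#' @param path output path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(G, "geno_matrix"))
  counts <- G$counts
  storage.mode(counts) <- "integer"
  if (dialect == "tsv") {
    df <- data.frame(id = G$ind_ids, counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = G$ind_ids, IID = G$ind_ids, PAT = 0, MAT = 0,
                     SEX = 0, PHENOTYPE = -9, counts, check.names = FALSE)
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control filter on SNPs and individuals
#'
#' SNPs failing the minor-allele-frequency or call-rate thresholds are
#' removed first; individuals failing the call-rate threshold on the
#' retained SNPs are removed next; allele frequencies are recomputed once on
#' the final matrix.
#'
#' @param G a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param snp_call_min minimum SNP call rate (default 0.95).
#' @param ind_call_min minimum individual call rate (default 0.95).
#' @return A list with elements `geno` (filtered [geno_matrix()]) and
#'   `report` (a `dirdom_qc` object).
#' @export
qc_filter <- function(G, maf_min = 0.05, snp_call_min = 0.95,
                      ind_call_min = 0.95) {
  stopifnot(inherits(G, "geno_matrix"))
  counts <- G$counts
  maf <- pmin(G$freqs, 1 - G$freqs)
  snp_call <- colMeans(!is.na(counts))
  drop_snp <- maf < maf_min | snp_call < snp_call_min
  if (all(drop_snp))
    stop("QC removed every SNP (maf_min = ", maf_min,
         ", snp_call_min = ", snp_call_min, ")")
  counts2 <- counts[, !drop_snp, drop = FALSE]
  ind_call <- rowMeans(!is.na(counts2))
  drop_ind <- ind_call < ind_call_min
  if (all(drop_ind)) stop("QC removed every individual (ind_call_min = ",
                          ind_call_min, ")")
  out <- geno_matrix(counts2[!drop_ind, , drop = FALSE],
                     ind_ids = G$ind_ids[!drop_ind],
                     snp_ids = G$snp_ids[!drop_snp])
  report <- structure(list(n_snp_in = ncol(counts), n_snp_out = ncol(counts2),
                           n_ind_in = nrow(counts), n_ind_out = sum(!drop_ind),
                           removed_snp_ids = G$snp_ids[drop_snp],
                           removed_ind_ids = G$ind_ids[drop_ind],
                           thresholds = c(maf_min = maf_min,
                                          snp_call_min = snp_call_min,
                                          ind_call_min = ind_call_min)),
                      class = "dirdom_qc")
  list(geno = out, report = report)
}

#' @export
print.dirdom_qc <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.dirdom_qc <- function(x, ...) {
  c(paste0("n_snp_in: ", x$n_snp_in),
    paste0("n_snp_out: ", x$n_snp_out),
    paste0("n_ind_in: ", x$n_ind_in),
    paste0("n_ind_out: ", x$n_ind_out),
    paste0("maf_min: ", x$thresholds[["maf_min"]]),
    paste0("snp_call_min: ", x$thresholds[["snp_call_min"]]),
    paste0("ind_call_min: ", x$thresholds[["ind_call_min"]]),
    paste0("removed_snp_ids: ", paste(x$removed_snp_ids, collapse = ",")),
    paste0("removed_ind_ids: ", paste(x$removed_ind_ids, collapse = ",")))
}

#' Average SNP homozygosity per individual
#'
#' The genomic-inbreeding covariate: the fraction of an individual's
#' non-missing SNP calls that are homozygous (count 0 or 2).  Missing calls
#' are excluded from both numerator and denominator.
#'
#' @param G a [geno_matrix()], normally after QC.
#' @return Named numeric vector in `[0, 1]`, one value per individual.
#' @export
homozygosity <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  nonmiss <- rowSums(!is.na(G$counts))
  if (any(nonmiss == 0))
    stop("individual(s) with zero non-missing calls: ",
         paste(head(G$ind_ids[nonmiss == 0], 5), collapse = ", "))
  hom <- rowSums(G$counts == 0 | G$counts == 2, na.rm = TRUE)
  stats::setNames(hom / nonmiss, G$ind_ids)
}

#' Additive and dominance design codes
#'
#' Returns the genotypic parameterisation used by the sampler: the additive
#' code is the allele count and the dominance code the heterozygote
#' indicator.  With `centering = "freq"` the codes are centred at their
#' Hardy-Weinberg expectations, `Z = x - 2p` and `K = 1(x == 1) - 2pq`, so
#' the general mean absorbs the population mean.  Missing genotypes are
#' mean-imputed (to `2p` and `2pq`), which makes their centred codes exactly
#' zero.
#'
#' @param G a [geno_matrix()] after QC (no monomorphic SNPs).
#' @param centering `"freq"` (default) or `"none"`.
#' @return List with matrices `Z` and `K` (individuals x SNPs).
#' @export
encode_design <- function(G, centering = c("freq", "none")) {
  centering <- match.arg(centering)
  stopifnot(inherits(G, "geno_matrix"))
  p <- G$freqs
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP(s) present (frequency 0 or 1): ",
         paste(head(G$snp_ids[p <= 0 | p >= 1], 5), collapse = ", "),
         "; run qc_filter() first")
  x <- G$counts
  het <- (x == 1) * 1.0
  twopq <- 2 * p * (1 - p)
  if (centering == "freq") {
    Z <- sweep(x, 2L, 2 * p, "-")
    K <- sweep(het, 2L, twopq, "-")
    Z[is.na(Z)] <- 0
    K[is.na(K)] <- 0
  } else {
    Z <- x
    K <- het
    miss <- is.na(x)
    if (any(miss)) {
      Z[miss] <- rep(2 * p, each = nrow(x))[miss]
      K[miss] <- rep(twopq, each = nrow(x))[miss]
    }
  }
  list(Z = Z, K = K)
}
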