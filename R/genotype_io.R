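# EIGENSTRAT genotype I/O, site/sample filters and analysis grouping.

TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")

is_transversion_pair <- function(a1, a2) {
  !(paste0(a1, a2) %in% TRANSITION_PAIRS)
}

#' Construct a genotype dataset
#'
#' Bundles a SNP map, a sample table and a genotype matrix into the
#' container used by every statistic in the package, validating the
#' invariants of the representation.
#'
#' Genotype codes follow the EIGENSTRAT convention: the value is the number
#' of copies of `allele1` (the first allele listed in the `.snp` file),
#' `NA` encodes a missing genotype (written as `9` on disk).  Samples with
#' `ploidy_mode == "pseudo_haploid"` represent one randomly drawn allele
#' per site and therefore only carry codes 0, 2 or `NA`.
#'
#' @param snp data frame with columns `snp_id`, `chrom`, `genetic_pos`,
#'   `physical_pos` (1-based), `allele1`, `allele2`.  A logical
#'   `is_transversion` column is derived from the allele pair.
#' @param sample data frame with columns `sample_id`, `sex` (`M`/`F`/`U`),
#'   `group_label`, optional `regional_label`, and `ploidy_mode`
#'   (`"diploid"` or `"pseudo_haploid"`).
#' @param geno integer matrix, samples in rows, SNPs in columns, entries in
#'   `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(snp, sample, geno) {
  snp <- as.data.frame(snp)
  sample <- as.data.frame(sample)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  required <- c("snp_id", "chrom", "genetic_pos", "physical_pos",
                "allele1", "allele2")
  miss <- setdiff(required, names(snp))
  if (length(miss)) stopf("snp table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group_label", "ploidy_mode") %in% names(sample)))
    stopf("sample table needs sample_id, group_label, ploidy_mode")
  if (is.null(sample$sex)) sample$sex <- "U"
  if (is.null(sample$regional_label)) sample$regional_label <- NA_character_
  if (any(snp$allele1 == snp$allele2))
    stopf("allele1 == allele2 at SNP(s): %s",
          paste(head(snp$snp_id[snp$allele1 == snp$allele2]), collapse = ", "))
  snp$is_transversion <- is_transversion_pair(snp$allele1, snp$allele2)
  if (nrow(geno) != nrow(sample) || ncol(geno) != nrow(snp))
    stopf("genotype matrix is %d x %d but there are %d samples and %d SNPs",
          nrow(geno), ncol(geno), nrow(sample), nrow(snp))
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stopf("genotype entries must be 0, 1, 2 or NA")
  ph <- sample$ploidy_mode == "pseudo_haploid"
  if (any(ph) && any(geno[ph, , drop = FALSE] == 1L, na.rm = TRUE))
    stopf("pseudo-haploid sample(s) carry heterozygous genotypes: %s",
          paste(sample$sample_id[ph][rowSums(geno[ph, , drop = FALSE] == 1L,
                                             na.rm = TRUE) > 0], collapse = ", "))
  # SNPs must be position-sorted within each chromosome for block building
  for (ch in unique(snp$chrom)) {
    pp <- snp$physical_pos[snp$chrom == ch]
    if (is.unsorted(pp)) stopf("SNPs on chromosome %s are not position-sorted", ch)
  }
  rownames(geno) <- sample$sample_id
  colnames(geno) <- snp$snp_id
  structure(list(snp = snp, sample = sample, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs (%d groups, %d transversion SNPs)\n",
              nrow(x$sample), nrow(x$snp), length(unique(x$sample$group_label)),
              sum(x$snp$is_transversion)))
  invisible(x)
}

#' Read an EIGENSTRAT genotype triple
#'
#' Reads `.geno` / `.snp` / `.ind` text files into a [genotype_dataset()].
#' Genotype digits count copies of the first allele listed in the `.snp`
#' file; `9` is read as missing.
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @param ploidy `"infer"` (a sample with no heterozygous call is treated as
#'   pseudo-haploid), `"diploid"`, `"pseudo_haploid"`, or a character vector
#'   with one mode per sample.
#' @return A `genotype_dataset`.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = "infer") {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  snp <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("snp_id", "chrom", "genetic_pos",
                                  "physical_pos", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  ind <- read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample_id", "sex", "group_label"),
                    colClasses = "character")
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stopf("format error: %s has %d rows but %s lists %d SNPs (first mismatch at line %d)",
          geno_path, length(lines), snp_path, nrow(snp),
          min(length(lines), nrow(snp)) + 1L)
  widths <- nchar(lines)
  if (length(lines) && any(widths != nrow(ind)))
    stopf("format error: %s line %d has %d genotypes but %s lists %d samples",
          geno_path, which(widths != nrow(ind))[1],
          widths[which(widths != nrow(ind))[1]], ind_path, nrow(ind))
  chars <- unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE)
  bad <- !(chars %in% c("0", "1", "2", "9"))
  if (any(bad)) {
    off <- which(bad)[1]
    stopf("parse error: non-genotype character '%s' in %s at line %d, column %d",
          chars[off], geno_path, (off - 1L) %/% nrow(ind) + 1L,
          (off - 1L) %% nrow(ind) + 1L)
  }
  g <- as.integer(chars)
  g[g == 9L] <- NA_integer_
  # .geno rows are SNPs; transpose to samples x SNPs
  geno <- matrix(g, nrow = nrow(ind), ncol = nrow(snp))
  if (identical(ploidy, "infer")) {
    het <- rowSums(geno == 1L, na.rm = TRUE) > 0
    ind$ploidy_mode <- ifelse(het, "diploid", "pseudo_haploid")
  } else if (length(ploidy) == 1L) {
    ind$ploidy_mode <- ploidy
  } else {
    if (length(ploidy) != nrow(ind))
      stopf("ploidy vector has length %d for %d samples", length(ploidy), nrow(ind))
    ind$ploidy_mode <- ploidy
  }
  genotype_dataset(snp, ind, geno)
}

#' Write a genotype dataset as an EIGENSTRAT triple
#'
#' Missing genotypes are written as `9`.  Re-reading the emitted files (with
#' the matching `ploidy` argument) reproduces the dataset.
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix output path prefix; `<prefix>.geno/.snp/.ind` are written.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_eigenstrat <- function(dataset, prefix) {
  g <- t(dataset$geno)            # SNP rows on disk
  g[is.na(g)] <- 9L
  lines <- apply(g, 1L, paste, collapse = "")
  paths <- c(geno = paste0(prefix, ".geno"),
             snp = paste0(prefix, ".snp"),
             ind = paste0(prefix, ".ind"))
  tryCatch({
    writeLines(lines, paths["geno"])
    snp <- dataset$snp
    write.table(
      data.frame(snp$snp_id, snp$chrom,
                 formatC(snp$genetic_pos, format = "g", digits = 15),
                 snp$physical_pos, snp$allele1, snp$allele2),
      paths["snp"], quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(dataset$sample[, c("sample_id", "sex", "group_label")],
                paths["ind"], quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }, error = function(e) stopf("cannot write EIGENSTRAT files at prefix %s: %s",
                               prefix, conditionMessage(e)))
  invisible(paths)
}

#' Restrict a dataset to transversion SNPs
#'
#' Transition SNPs (A/G and C/T pairs) are the sites affected by
#' characteristic post-mortem cytosine deamination errors in ancient DNA;
#' dropping them is the standard robustness filter.
#'
#' @param dataset a `genotype_dataset`.
#' @return The dataset restricted to SNPs whose allele pair is a
#'   transversion; the sample set is unchanged.
#' @export
restrict_to_transversions <- function(dataset) {
  keep <- dataset$snp$is_transversion
  genotype_dataset(dataset$snp[keep, , drop = FALSE], dataset$sample,
                   dataset$geno[, keep, drop = FALSE])
}

#' Randomly haploidize diploid genotypes
#'
#' Replaces every heterozygous genotype by 0 or 2 with probability 1/2
#' each, emulating the representation of a sample by a single randomly
#' drawn allele per site.  Homozygous and missing entries are unchanged.
#'
#' @param dataset a `genotype_dataset` with diploid samples.
#' @param seed integer seed controlling the random draws.
#' @return The dataset with all samples marked `pseudo_haploid`.
#' @export
pseudo_haploidize <- function(dataset, seed) {
  g <- dataset$geno
  het <- which(!is.na(g) & g == 1L)
  with_seed(seed, {
    g[het] <- 2L * rbinom(length(het), 1L, 0.5)
  })
  sample <- dataset$sample
  sample$ploidy_mode <- "pseudo_haploid"
  genotype_dataset(dataset$snp, sample, g)
}

#' Re-label samples into analysis groups
#'
#' Pools individuals into analysis clusters (e.g. by site and time period)
#' by replacing their group and regional labels.
#'
#' @param dataset a `genotype_dataset`.
#' @param label_map data frame with columns `sample_id`, `group_label` and
#'   optionally `regional_label`.  Every sample of the dataset must appear;
#'   map rows for unknown samples raise a warning.
#' @return The re-labelled dataset.
#' @export
assign_groups <- function(dataset, label_map) {
  label_map <- as.data.frame(label_map)
  if (!all(c("sample_id", "group_label") %in% names(label_map)))
    stopf("label_map needs sample_id and group_label columns")
  unknown <- setdiff(label_map$sample_id, dataset$sample$sample_id)
  if (length(unknown))
    warnf("label_map rows for unknown sample(s) ignored: %s",
          paste(unknown, collapse = ", "))
  missing <- setdiff(dataset$sample$sample_id, label_map$sample_id)
  if (length(missing))
    stopf("sample(s) missing from label_map: %s", paste(missing, collapse = ", "))
  idx <- match(dataset$sample$sample_id, label_map$sample_id)
  sample <- dataset$sample
  sample$group_label <- label_map$group_label[idx]
  if (!is.null(label_map$regional_label))
    sample$regional_label <- label_map$regional_label[idx]
  if (any(!nzchar(sample$group_label)))
    stopf("empty group_label for sample(s): %s",
          paste(sample$sample_id[!nzchar(sample$group_label)], collapse = ", "))
  genotype_dataset(dataset$snp, sample, dataset$geno)
}
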