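# Readers and writers for the plain-text interchange formats the pipeline
# uses: long-format plate CSV/TSV, trait TSV, genotype TSV (strains x sites),
# strain metadata TSV, Newick dendrograms, JSON summaries.

.read_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a long-format plate table
#'
#' Reads a CSV/TSV with one OD reading per row and validates it: the
#' required columns must be present, each well's time series is sorted by
#' time (with a warning when re-ordering was needed), and duplicated
#' (strain, condition, replicate, time) readings are an error.
#'
#' @param path Path to the plate file. Columns: `strain`, `condition`,
#'   `replicate`, `time_hr`, `od`, optional `blank`.
#' @return The validated plate data frame, sorted by well and time.
#' @export
read_plate_table <- function(path) {
  x <- .read_any(path)
  req <- c("strain", "condition", "replicate", "time_hr", "od")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("plate table is missing column(s): ", paste(miss, collapse = ", "),
         " (expected header: ", paste(req, collapse = ", "), "[, blank])")
  key <- paste(x$strain, x$condition, x$replicate, sep = "\r")
  dup <- duplicated(paste(key, x$time_hr))
  if (any(dup))
    stop("duplicated (strain, condition, replicate, time) reading(s), e.g. ",
         gsub("\r", "/", paste(key[dup][1], x$time_hr[dup][1])))
  ord <- order(x$strain, x$condition, x$replicate, x$time_hr)
  resorted <- any(tapply(x$time_hr, key, function(tt) is.unsorted(tt)))
  if (isTRUE(resorted))
    warning("time points were not sorted within wells; reordering")
  x <- x[ord, ]
  rownames(x) <- NULL
  x
}

#' Write / read a morphological trait table
#'
#' Tab-separated, columns `strain`, `replicate`, then one column per trait.
#' @param table Trait table data frame.
#' @param path File path.
#' @return `read_trait_table` returns the data frame.
#' @export
write_trait_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  x <- .read_any(path)
  .trait_cols(x)  # validates
  x
}

#' Write / read a genotype matrix
#'
#' Tab-separated, first column `strain`, then one 0/1 (or NA) column per
#' site.
#' @param g Strains x sites matrix.
#' @param path File path.
#' @return `read_genotype_matrix` returns a `genotype_matrix`.
#' @export
write_genotype_matrix <- function(g, path) {
  df <- data.frame(strain = rownames(g), as.data.frame(unclass(g)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  x <- .read_any(path)
  if (names(x)[1] != "strain") stop("first column must be 'strain'")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$strain
  storage.mode(m) <- "integer"
  if (any(!(m %in% c(0L, 1L, NA))))
    stop("genotype entries must be 0, 1 or NA")
  structure(m, class = c("genotype_matrix", "matrix", "array"))
}

#' Read haploid biallelic genotypes from a VCF file
#'
#' Accepts only biallelic SNP records with haploid (or fully homozygous)
#' genotypes; all other records are skipped and counted. Requires the
#' `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A `genotype_matrix` (strains x sites) with attribute
#'   `skipped` counting the records discarded per reason.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ref <- vcfR::getREF(v); alt <- vcfR::getALT(v)
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))[snp]
  conv <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0", "0/0")] <- 0L
    out[x %in% c("1", "1/1")] <- 1L
    out
  }
  m <- apply(gt, 2, conv)
  if (is.null(dim(m))) m <- matrix(m, nrow = sum(snp))
  het <- sum(gt %in% c("0/1", "1/0", "0|1", "1|0"))
  g <- t(m)
  colnames(g) <- ids
  rownames(g) <- colnames(gt)
  structure(g, skipped = c(non_biallelic_snp = sum(!snp), heterozygous = het),
            class = c("genotype_matrix", "matrix", "array"))
}

#' Export a dendrogram as Newick plus a merge table
#'
#' @param h An [stats::hclust] object.
#' @param newick_path Path for the Newick tree.
#' @param merge_path Optional path for a TSV of the merge heights.
#' @return Invisibly, `newick_path`.
#' @export
write_dendrogram <- function(h, newick_path, merge_path = NULL) {
  ape::write.tree(ape::as.phylo(h), file = newick_path)
  if (!is.null(merge_path)) {
    mt <- data.frame(step = seq_along(h$height), left = h$merge[, 1],
                     right = h$merge[, 2], height = h$height)
    utils::write.table(mt, merge_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(newick_path)
}

#' Read a strain metadata table
#'
#' TSV with columns `strain`, `geography`, `ecology` and optionally
#' `subgroup`.
#' @param path File path.
#' @return Data frame.
#' @export
read_strain_metadata <- function(path) {
  x <- .read_any(path)
  req <- c("strain", "geography", "ecology")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  x
}
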