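#' @importFrom utils read.delim write.table
NULL

#' Read / write chromatograms as two-column delimited text
#'
#' Tab-separated, header `rt` (minutes) and `intensity`.
#'
#' @param path File path.
#' @param sample_id Label attached on read (defaults to the file stem).
#' @return [read_chromatogram()]: a [chromatogram()].
#' @export
read_chromatogram <- function(path, sample_id = NULL) {
  d <- read.delim(path)
  if (!all(c("rt", "intensity") %in% names(d)))
    stop("chromatogram file needs columns rt, intensity")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  chromatogram(d$rt, d$intensity, sample_id = sample_id)
}

#' @rdname read_chromatogram
#' @param chrom A [chromatogram()].
#' @export
write_chromatogram <- function(chrom, path) {
  write.table(data.frame(rt = chrom$rt, intensity = chrom$intensity),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write MRM transition tables as delimited text
#'
#' Tab-separated, header `precursor_mz`, `product_mz`, `intensity`.
#'
#' @param path File path.
#' @return [read_transitions()]: a data.frame.
#' @export
read_transitions <- function(path) {
  d <- read.delim(path)
  need <- c("precursor_mz", "product_mz", "intensity")
  if (!all(need %in% names(d)))
    stop("transition file needs columns precursor_mz, product_mz, intensity")
  d[need]
}

#' @rdname read_transitions
#' @param transitions data.frame with the three transition columns.
#' @export
write_transitions <- function(transitions, path) {
  write.table(transitions, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a simulated study to a directory of delimited files
#'
#' One chromatogram and one transition table per sample, the qPCR /
#' feature-count / gene-count tables, and a JSON manifest listing per-sample
#' file paths and ground-truth labels.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- study$samples$sample_id
  chrom_files <- file.path("chromatograms", paste0(ids, ".tsv"))
  mrm_files <- file.path("mrm", paste0(ids, ".tsv"))
  dir.create(file.path(dir, "chromatograms"), showWarnings = FALSE)
  dir.create(file.path(dir, "mrm"), showWarnings = FALSE)
  for (i in seq_along(ids)) {
    write_chromatogram(study$chromatograms[[i]],
                       file.path(dir, chrom_files[i]))
    write_transitions(study$mrm[[i]], file.path(dir, mrm_files[i]))
  }
  write.table(study$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = rownames(study$features),
                         study$features, check.names = FALSE),
              file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(study$gene_counts, file.path(dir, "gene_counts.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    n_samples = length(ids),
    tables = list(qpcr = "qpcr.tsv", features = "features.tsv",
                  gene_counts = "gene_counts.tsv"),
    samples = lapply(seq_along(ids), function(i) list(
      sample_id = ids[i],
      oilfield = study$samples$oilfield[i],
      sample_type = study$samples$sample_type[i],
      chromatogram = chrom_files[i],
      mrm = mrm_files[i],
      truth = list(
        degradation_degree = study$samples$degradation_degree[i],
        planted_alkylcom_chain_lengths =
          study$truth[[i]]$planted_alkylcom_chain_lengths,
        true_16S_copies_per_g = study$truth[[i]]$true_16S_copies_per_g,
        true_relabund = study$truth[[i]]$true_relabund,
        true_fpkm = as.list(study$truth[[i]]$true_fpkm)))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
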