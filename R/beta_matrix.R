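#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` bundles a probes x samples matrix of methylation beta
#' values (the fraction of methylated signal at a CpG probe, 0 = fully
#' unmethylated, 1 = fully methylated) with per-sample metadata. Missing
#' measurements are allowed and encoded as `NA`; they are excluded pairwise
#' in all downstream statistics.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are required and must be unique; every non-missing value
#'   must lie in `[0, 1]`.
#' @param sample_meta Data frame with columns `sample_id`, `group` (one of
#'   `"case"` or `"control"`) and optionally `sex` (`"F"`/`"M"` or `NA`).
#'   Every column of `values` must have a metadata row.
#' @param genome_build Label stored as metadata and echoed by writers
#'   (coordinates in companion manifests are interpreted in this build).
#'
#' @return An object of class `beta_matrix`: a list with elements `values`,
#'   `sample_meta` (tibble) and `genome_build`.
#' @export
#' @examples
#' m <- matrix(c(0.55, 0.01, 0.5, 0.5), nrow = 2,
#'             dimnames = list(c("cg0001", "cg0002"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    group = c("case", "control"))
#' bm <- beta_matrix(m, meta)
#' n_samples(bm)
beta_matrix <- function(values, sample_meta, genome_build = "GRCh37") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in beta matrix", call. = FALSE)

  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]), call. = FALSE)
  }

  sample_meta <- tibble::as_tibble(sample_meta)
  req <- c("sample_id", "group")
  if (!all(req %in% names(sample_meta)))
    stop("sample metadata needs columns 'sample_id' and 'group'",
         call. = FALSE)
  if (!"sex" %in% names(sample_meta)) sample_meta$sex <- NA_character_
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta) > 0)
    stop(sprintf("samples without metadata: %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  if (!all(sample_meta$group %in% c("case", "control")))
    stop("sample group must be 'case' or 'control'", call. = FALSE)

  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  structure(list(values = values,
                 sample_meta = sample_meta,
                 genome_build = genome_build),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  ncase <- sum(x$sample_meta$group == "case")
  cat(sprintf("beta_matrix: %d probes x %d samples (%d cases, %d controls), build %s\n",
              nrow(x$values), ncol(x$values), ncase,
              ncol(x$values) - ncase, x$genome_build))
  invisible(x)
}

#' @rdname beta_matrix
#' @param x A `beta_matrix`.
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname beta_matrix
#' @export
n_probes <- function(x) nrow(x$values)

#' Column indices of case / control samples
#' @param x A `beta_matrix`.
#' @return Integer indices into the columns of `x$values`.
#' @keywords internal
case_idx <- function(x) which(x$sample_meta$group == "case")

#' @rdname case_idx
#' @keywords internal
control_idx <- function(x) which(x$sample_meta$group == "control")

.delim_char <- function(format = c("tsv", "csv")) {
  switch(match.arg(format), tsv = "\t", csv = ",")
}

.version_header <- function(genome_build) {
  sprintf("# epimutr %s; genome_build=%s",
          as.character(utils::packageVersion("epimutr")), genome_build)
}

#' Read a beta-value matrix and its sample metadata
#'
#' The matrix file is delimited text with the probe id in the first column
#' and one column per sample; empty cells are parsed as missing (`NA`),
#' never as 0. The metadata file maps `sample_id` to `group`
#' (case/control) and optional `sex`. Lines starting with `#` are ignored
#' in both files.
#'
#' @param path Path to the beta matrix file.
#' @param meta_path Path to the sample metadata file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param genome_build Genome-build label to attach.
#' @return A validated [beta_matrix()].
#' @export
read_beta_matrix <- function(path, meta_path, format = c("tsv", "csv"),
                             genome_build = "GRCh37") {
  sep <- .delim_char(format)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  probe_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  beta_matrix(values, meta, genome_build = genome_build)
}

#' Write a beta-value matrix and its sample metadata
#'
#' Both files start with a `#` header comment recording the package version
#' and genome-build label. Missing values are written as empty cells.
#'
#' @param x A [beta_matrix()].
#' @param path,meta_path Output paths for the matrix and metadata tables.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `x`, invisibly.
#' @export
write_beta_matrix <- function(x, path, meta_path, format = c("tsv", "csv")) {
  sep <- .delim_char(format)
  hdr <- .version_header(x$genome_build)

  con <- file(path, "w")
  writeLines(hdr, con)
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  close(con)

  con <- file(meta_path, "w")
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x$sample_meta), con, sep = sep,
                     quote = FALSE, row.names = FALSE, na = "")
  close(con)
  invisible(x)
}
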