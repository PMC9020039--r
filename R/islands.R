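#' Read CpG-island intervals from a BED-like file
#'
#' BED uses 0-based half-open coordinates; internally the package works in
#' 1-based inclusive coordinates (the convention of array manifests and the
#' printed positions this package reproduces). The conversion is
#' `start = bed_start + 1`, `end = bed_end`, a bijection that preserves
#' interval length (`end - start + 1 == bed_end - bed_start`).
#'
#' @param path BED-like delimited text with at least four columns:
#'   chromosome, start, end, island id. Lines starting with `#` or `track`
#'   are skipped.
#' @return A tibble (class `cpg_island_set`) with columns `island_id`,
#'   `chromosome`, `start`, `end` (1-based inclusive).
#' @export
read_islands <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no intervals in BED file", call. = FALSE)
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) < 4))
    stop("BED file needs 4 columns: chrom, start, end, name", call. = FALSE)
  bed_start <- as.numeric(vapply(parts, `[[`, "", 2))
  bed_end <- as.numeric(vapply(parts, `[[`, "", 3))
  out <- tibble::tibble(
    island_id = vapply(parts, `[[`, "", 4),
    chromosome = vapply(parts, `[[`, "", 1),
    start = bed_start + 1,
    end = bed_end)
  cpg_island_set(out)
}

#' Validate a set of CpG-island intervals
#'
#' @param x Data frame with columns `island_id`, `chromosome`, `start`,
#'   `end` in 1-based inclusive coordinates.
#' @return The validated tibble with class `cpg_island_set` prepended.
#' @export
cpg_island_set <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("island_id", "chromosome", "start", "end")
  if (!all(req %in% names(x)))
    stop("island set needs columns island_id, chromosome, start, end",
         call. = FALSE)
  if (anyDuplicated(x$island_id))
    stop("duplicate island ids", call. = FALSE)
  if (any(x$start > x$end))
    stop(sprintf("empty or inverted interval for island '%s'",
                 x$island_id[which(x$start > x$end)[1]]), call. = FALSE)
  if (any(x$start < 1)) stop("island start below 1", call. = FALSE)
  class(x) <- unique(c("cpg_island_set", class(x)))
  x
}

#' Write CpG-island intervals as BED
#'
#' Inverse of [read_islands()]: converts the internal 1-based inclusive
#' coordinates back to 0-based half-open BED.
#'
#' @param islands A [cpg_island_set()].
#' @param path Output path.
#' @param genome_build Build label written in the header comment.
#' @return `islands`, invisibly.
#' @export
write_islands <- function(islands, path, genome_build = "GRCh37") {
  con <- file(path, "w")
  writeLines(.version_header(genome_build), con)
  utils::write.table(
    data.frame(islands$chromosome, islands$start - 1, islands$end,
               islands$island_id),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(islands)
}

#' Validate a probe manifest
#'
#' @param x Data frame with columns `probe_id`, `chromosome`, `position`
#'   (1-based bp) and optionally `island_relation`, `island_id`,
#'   `flank_distance` as produced by [map_probes_to_islands()].
#' @return Validated tibble with class `probe_manifest`.
#' @export
probe_manifest <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("probe_id", "chromosome", "position")
  if (!all(req %in% names(x)))
    stop("manifest needs columns probe_id, chromosome, position",
         call. = FALSE)
  if (anyDuplicated(x$probe_id)) stop("duplicate probe ids", call. = FALSE)
  if (any(x$position < 1)) stop("probe position below 1", call. = FALSE)
  class(x) <- unique(c("probe_manifest", class(x)))
  x
}

#' Read / write a probe manifest
#'
#' @param path Manifest file: delimited text with columns `probe_id`,
#'   `chromosome`, `position` and optional island-relation columns.
#' @param format `"tsv"` or `"csv"`.
#' @return [read_manifest()] returns a validated [probe_manifest()] tibble.
#' @export
read_manifest <- function(path, format = c("tsv", "csv")) {
  sep <- .delim_char(format)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  probe_manifest(tab)
}

#' @rdname read_manifest
#' @param manifest A [probe_manifest()].
#' @param genome_build Build label written in the header comment.
#' @export
write_manifest <- function(manifest, path, format = c("tsv", "csv"),
                           genome_build = "GRCh37") {
  sep <- .delim_char(format)
  con <- file(path, "w")
  writeLines(.version_header(genome_build), con)
  utils::write.table(as.data.frame(manifest), con, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  invisible(manifest)
}

#' Assign every probe an island relation
#'
#' Partitions probes into `in_island` (position within an island interval),
#' `flank` (within `flank_bp` of the nearest island edge — this is how the
#' "upstream 5' end" probes adjacent to a promoter island are captured;
#' flanking is symmetric and strand-agnostic) and `open_sea` (everything
#' else). Distances are plain coordinate differences to the nearest island
#' edge (a probe one bp past an island end has distance 1). When a probe is
#' equidistant or within reach of several islands, the nearest edge wins;
#' exact ties go to the island that comes first in `islands`.
#'
#' @param manifest A [probe_manifest()].
#' @param islands A [cpg_island_set()].
#' @param flank_bp Non-negative flank width in bp (default 250).
#' @return The manifest with columns `island_relation`
#'   (`in_island`/`flank`/`open_sea`), `island_id` (`NA` for open sea) and
#'   `flank_distance` (bp to the nearest edge; 0 inside an island, `NA` for
#'   open sea).
#' @export
map_probes_to_islands <- function(manifest, islands, flank_bp = 250) {
  manifest <- probe_manifest(manifest)
  islands <- cpg_island_set(islands)
  if (flank_bp < 0) stop("flank_bp must be >= 0", call. = FALSE)

  n <- nrow(manifest)
  best_dist <- rep(Inf, n)
  best_island <- rep(NA_character_, n)
  for (i in seq_len(nrow(islands))) {
    on_chr <- manifest$chromosome == islands$chromosome[i]
    pos <- manifest$position
    d <- ifelse(pos < islands$start[i], islands$start[i] - pos,
                ifelse(pos > islands$end[i], pos - islands$end[i], 0))
    d[!on_chr] <- Inf
    take <- d < best_dist
    best_dist[take] <- d[take]
    best_island[take] <- islands$island_id[i]
  }

  relation <- ifelse(best_dist == 0, "in_island",
                     ifelse(best_dist <= flank_bp, "flank", "open_sea"))
  manifest$island_relation <- relation
  manifest$island_id <- ifelse(relation == "open_sea", NA_character_,
                               best_island)
  manifest$flank_distance <- ifelse(relation == "open_sea", NA_real_,
                                    best_dist)
  manifest
}
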