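#' Three-state classification of a methylation beta value
#'
#' A probe with beta below `low` is fully unmethylated; above `high` it is
#' fully methylated; anything in the closed interval `[low, high]` is
#' hemimethylated — the intermediate level expected when exactly one of the
#' two alleles carries the methylation mark. The defaults 0.2 and 0.6 are
#' the thresholds used throughout the package's epigram-style summaries;
#' both boundary values classify as hemimethylated.
#'
#' @param beta Numeric vector of beta values in `[0, 1]`.
#' @param low,high State thresholds, `0 < low < high < 1`.
#' @return An ordered factor with levels
#'   `fully_unmethylated < hemimethylated < fully_methylated`.
#' @export
#' @examples
#' classify_beta(c(0.01, 0.55, 0.61))
classify_beta <- function(beta, low = 0.2, high = 0.6) {
  if (!(low > 0 && high < 1 && low < high))
    stop("thresholds must satisfy 0 < low < high < 1", call. = FALSE)
  if (anyNA(beta) || any(beta < 0 | beta > 1))
    stop("beta values must lie in [0,1] and be non-missing", call. = FALSE)
  states <- ifelse(beta < low, "fully_unmethylated",
                   ifelse(beta > high, "fully_methylated", "hemimethylated"))
  factor(states, levels = c("fully_unmethylated", "hemimethylated",
                            "fully_methylated"), ordered = TRUE)
}

.modal_state <- function(states) {
  tab <- table(states)
  names(tab)[which.max(tab)]
}

#' Call an epimutation at one CpG island
#'
#' Converts the per-probe EWAS rows of a single island (in-island plus
#' flank probes) into an island-level verdict. A probe is *concordant*
#' when its control group mean is fully unmethylated while its case group
#' mean is hemimethylated or fully methylated — the aberrant-gain pattern
#' of a promoter epimutation (a bi-allelic epimutation pushes the case mean
#' above the fully-methylated threshold, so both states count). A probe is
#' *significant* when its Bonferroni-corrected P is below `alpha`. The
#' verdict is `epimutated` when the island has at least `min_probes`
#' probes, the concordant fraction reaches `min_fraction_concordant` and at
#' least `require_significant` probes are significant; with fewer than
#' `min_probes` probes it is `insufficient_probes`.
#'
#' @param rows EWAS rows (see [run_ewas()]) all mapping to one island.
#' @param alpha Significance level on the Bonferroni-corrected P.
#' @param min_fraction_concordant Required concordant fraction (default 1:
#'   every probe of the island must show the pattern).
#' @param min_probes Minimum probes for a confident call (default 3).
#' @param require_significant Minimum number of Bonferroni-significant
#'   probes (default 1).
#' @param low,high Classification thresholds, see [classify_beta()].
#' @return One-row tibble: `island_id`, `n_probes_considered`,
#'   `n_concordant`, `n_significant`, `case_state_summary`,
#'   `control_state_summary`, `min_p_nominal`, `verdict`.
#' @export
call_island <- function(rows, alpha = 0.05, min_fraction_concordant = 1.0,
                        min_probes = 3, require_significant = 1,
                        low = 0.2, high = 0.6) {
  rows <- tibble::as_tibble(rows)
  ids <- unique(rows$island_id)
  if (length(ids) != 1 || is.na(ids))
    stop("rows must all map to exactly one island", call. = FALSE)
  rows <- rows[!is.na(rows$mean_beta_cases) & !is.na(rows$mean_beta_controls), ]
  n <- nrow(rows)

  if (n == 0) {
    return(tibble::tibble(
      island_id = ids, n_probes_considered = 0L, n_concordant = 0L,
      n_significant = 0L, case_state_summary = NA_character_,
      control_state_summary = NA_character_, min_p_nominal = NA_real_,
      verdict = "insufficient_probes"))
  }

  case_state <- classify_beta(rows$mean_beta_cases, low, high)
  control_state <- classify_beta(rows$mean_beta_controls, low, high)
  concordant <- control_state == "fully_unmethylated" &
    case_state >= "hemimethylated"
  significant <- !is.na(rows$p_bonferroni) & rows$p_bonferroni < alpha

  verdict <- if (n < min_probes) {
    "insufficient_probes"
  } else if (sum(concordant) / n >= min_fraction_concordant &&
             sum(significant) >= require_significant) {
    "epimutated"
  } else {
    "not_epimutated"
  }

  tibble::tibble(
    island_id = ids,
    n_probes_considered = n,
    n_concordant = sum(concordant),
    n_significant = sum(significant),
    case_state_summary = .modal_state(case_state),
    control_state_summary = .modal_state(control_state),
    min_p_nominal = suppressWarnings(min(rows$p_nominal, na.rm = TRUE)),
    verdict = verdict)
}

#' Scan all islands for epimutations
#'
#' Groups EWAS rows by island (in-island and flank probes alike) and calls
#' [call_island()] on each island with at least one mapped probe. Calls are
#' returned sorted by the island's minimum nominal P (ties by island id),
#' so the strongest signatures come first.
#'
#' @param ewas Output of [run_ewas()].
#' @param islands A [cpg_island_set()]; only islands present here are
#'   called.
#' @param ... Passed to [call_island()].
#' @return Tibble of island calls.
#' @export
scan_genome <- function(ewas, islands, ...) {
  islands <- cpg_island_set(islands)
  ewas <- tibble::as_tibble(ewas)
  mapped <- ewas[!is.na(ewas$island_id) &
                   ewas$island_id %in% islands$island_id, ]
  if (nrow(mapped) == 0) {
    return(tibble::tibble(
      island_id = character(), n_probes_considered = integer(),
      n_concordant = integer(), n_significant = integer(),
      case_state_summary = character(), control_state_summary = character(),
      min_p_nominal = numeric(), verdict = character()))
  }
  calls <- lapply(split(mapped, mapped$island_id), call_island, ...)
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$min_p_nominal, calls$island_id), ]
  tibble::as_tibble(calls)
}

#' Write island calls as TSV and epimutated intervals as BED
#'
#' @param calls Output of [scan_genome()].
#' @param islands The [cpg_island_set()] the calls refer to.
#' @param path TSV output path.
#' @param bed_path Optional BED path for the `epimutated` islands.
#' @param genome_build Build label for header comments.
#' @return `calls`, invisibly.
#' @export
write_calls <- function(calls, islands, path, bed_path = NULL,
                        genome_build = "GRCh37") {
  con <- file(path, "w")
  writeLines(.version_header(genome_build), con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  if (!is.null(bed_path)) {
    hit <- islands[islands$island_id %in%
                     calls$island_id[calls$verdict == "epimutated"], ]
    write_islands(cpg_island_set(hit), bed_path, genome_build)
  }
  invisible(calls)
}
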