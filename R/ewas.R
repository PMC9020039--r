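#' Group mean beta values and their difference for one probe
#'
#' Missing values are excluded per group. `delta_beta` is the case mean
#' minus the control mean, the effect size printed alongside every probe in
#' the study's top-hit tables.
#'
#' @param bm A [beta_matrix()].
#' @param probe Probe id.
#' @return A list with `mean_cases`, `mean_controls`, `delta_beta`,
#'   `n_cases_used`, `n_controls_used`.
#' @export
probe_group_stats <- function(bm, probe) {
  if (!probe %in% rownames(bm$values))
    stop(sprintf("unknown probe '%s'", probe), call. = FALSE)
  v <- bm$values[probe, ]
  xc <- v[case_idx(bm)]; xk <- v[control_idx(bm)]
  nc <- sum(!is.na(xc)); nk <- sum(!is.na(xk))
  if (nc < 1 || nk < 1)
    stop(sprintf("probe '%s' has no non-missing values in one group", probe),
         call. = FALSE)
  mc <- mean(xc, na.rm = TRUE); mk <- mean(xk, na.rm = TRUE)
  list(mean_cases = mc, mean_controls = mk, delta_beta = mc - mk,
       n_cases_used = nc, n_controls_used = nk)
}

# Vectorized two-sample t statistics over the rows of a probes x samples
# matrix. Welch (unequal variances, Welch-Satterthwaite df) by default;
# "student" pools variances with n1 + n2 - 2 df. Degenerate rows with zero
# variance in both groups get t = 0, P = 1 when the means agree, and
# P = .Machine$double.xmin (t = +/-Inf) when they differ, keeping P in
# (0, 1].
.row_t_test <- function(values, idx1, idx2, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  x1 <- values[, idx1, drop = FALSE]; x2 <- values[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  testable <- n1 >= 2 & n2 >= 2

  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(t), df)

  degen <- testable & (v1 + v2) == 0
  eq <- degen & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  ne <- degen & (m1 != m2)
  t[ne] <- sign(m1 - m2)[ne] * Inf
  p[ne] <- .Machine$double.xmin
  p[testable] <- pmax(p[testable], .Machine$double.xmin)

  t[!testable] <- NA_real_; p[!testable] <- NA_real_
  list(t_stat = t, p_nominal = p, df = df,
       mean_1 = m1, mean_2 = m2, n_1 = n1, n_2 = n2, testable = testable)
}

#' Two-sample t-test of case versus control beta values at one probe
#'
#' @param bm A [beta_matrix()].
#' @param probe Probe id.
#' @param variant `"welch"` (default; unequal variances — a small patient
#'   group against a large population cohort rarely shares a variance) or
#'   `"student"` (classical pooled form).
#' @return A list with `t_stat`, `p_nominal` (two-sided, in `(0, 1]`) and
#'   `df`. Probes with fewer than two non-missing values in either group
#'   are not testable and raise an error (callers doing a genome-wide scan
#'   should use [run_ewas()], which flags such probes instead).
#' @export
probe_t_test <- function(bm, probe, variant = c("welch", "student")) {
  if (!probe %in% rownames(bm$values))
    stop(sprintf("unknown probe '%s'", probe), call. = FALSE)
  res <- .row_t_test(bm$values[probe, , drop = FALSE],
                     case_idx(bm), control_idx(bm), variant)
  if (!res$testable[1])
    stop(sprintf("probe '%s' has fewer than 2 values in a group", probe),
         call. = FALSE)
  list(t_stat = unname(res$t_stat[1]), p_nominal = unname(res$p_nominal[1]),
       df = unname(res$df[1]))
}

#' Bonferroni correction
#'
#' @param p_nominal Nominal P-value(s).
#' @param m_tests Number of probes actually tested (after missingness
#'   filtering), the multiplicity of the family.
#' @return `min(1, p_nominal * m_tests)`, vectorized.
#' @export
bonferroni <- function(p_nominal, m_tests) {
  if (m_tests < 1) stop("m_tests must be >= 1", call. = FALSE)
  pmin(1, p_nominal * m_tests)
}

#' Windowed smoothing of -log10 P-values along the genome
#'
#' Replaces each probe's `-log10(P)` with the mean over a window of
#' `radius` probes on each side (2r + 1 probes), computed per chromosome
#' with the window truncated at chromosome ends. Radius 0 is the identity.
#' Smoothed values accompany — never replace — the nominal and Bonferroni
#' P-values.
#'
#' @param rows Data frame sorted by `(chromosome, position)` with columns
#'   `chromosome`, `position`, `neglog10_p`.
#' @param radius Non-negative window radius in probes (default 3).
#' @return `rows` with a `neglog10_p_smoothed` column.
#' @export
smooth_p <- function(rows, radius = 3) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  rows <- tibble::as_tibble(rows)
  ord <- order(rows$chromosome, rows$position)
  if (any(ord != seq_len(nrow(rows))))
    stop("rows must be sorted by (chromosome, position)", call. = FALSE)

  out <- rep(NA_real_, nrow(rows))
  for (chr in unique(rows$chromosome)) {
    i <- which(rows$chromosome == chr)
    out[i] <- .moving_mean(rows$neglog10_p[i], radius)
  }
  rows$neglog10_p_smoothed <- out
  rows
}

# Truncated-window moving mean with NA exclusion, O(n) via cumulative sums.
.moving_mean <- function(v, r) {
  n <- length(v)
  if (r == 0) return(v)
  ok <- !is.na(v)
  cs <- cumsum(c(0, ifelse(ok, v, 0)))
  ck <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(1, seq_len(n) - r)
  hi <- pmin(n, seq_len(n) + r)
  s <- cs[hi + 1] - cs[lo]
  k <- ck[hi + 1] - ck[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Principal-component QC of methylation profiles
#'
#' Samples are projected on the top `k` principal components of the
#' probe-centered beta matrix (missing cells imputed with the probe mean
#' before decomposition). Used to check that samples cluster by phenotype
#' and sex rather than by batch, genome-wide or restricted to one
#' chromosome.
#'
#' @param bm A [beta_matrix()].
#' @param k Number of components (default 10, reported as EV1..EVk).
#' @param manifest Optional [probe_manifest()], needed for `chromosome`.
#' @param chromosome Optional chromosome label; restricts the decomposition
#'   to probes on that chromosome.
#' @return A list of class `pca_result` with `eigenvalues` (non-increasing,
#'   length `k`), `scores` (samples x k, columns EV1..EVk),
#'   `prop_variance`, `total_variance` and `sample_meta`.
#' @export
pca_qc <- function(bm, k = 10, manifest = NULL, chromosome = NULL) {
  values <- bm$values
  if (!is.null(chromosome)) {
    if (is.null(manifest))
      stop("chromosome filtering requires a manifest", call. = FALSE)
    keep <- manifest$probe_id[manifest$chromosome == chromosome]
    values <- values[rownames(values) %in% keep, , drop = FALSE]
    if (nrow(values) == 0)
      stop(sprintf("no probes on chromosome '%s'", chromosome), call. = FALSE)
  }
  if (any(colSums(!is.na(values)) == 0))
    stop("a sample has no non-missing values", call. = FALSE)

  all_missing <- rowSums(!is.na(values)) == 0
  values <- values[!all_missing, , drop = FALSE]
  if (anyNA(values)) {
    pm <- rowMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- pm[idx[, 1]]
  }

  k <- min(k, nrow(values), ncol(values) - 1)
  pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("EV%d", seq_len(k))
  structure(list(eigenvalues = eig[seq_len(k)],
                 scores = scores,
                 prop_variance = eig[seq_len(k)] / sum(eig),
                 total_variance = sum(eig),
                 sample_meta = bm$sample_meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components over %d samples\n",
              length(x$eigenvalues), nrow(x$scores)))
  cat("proportion of variance:",
      paste(sprintf("%.3f", x$prop_variance), collapse = " "), "\n")
  invisible(x)
}

#' Run the per-probe epigenome-wide association scan
#'
#' For every probe with at least two non-missing values per group this
#' computes the group mean betas, their difference, the two-sample t-test,
#' the Bonferroni-corrected P (multiplicity = number of probes actually
#' tested in this run) and the windowed smoothed `-log10(P)`. Probes
#' failing the missingness rule are kept in the output flagged
#' `tested = FALSE` with `NA` statistics, never silently given P = 1.
#'
#' @param bm A [beta_matrix()].
#' @param manifest A [probe_manifest()]; if it lacks island relations and
#'   `islands` is supplied, [map_probes_to_islands()] is applied first.
#' @param islands Optional [cpg_island_set()].
#' @param variant t-test flavor, `"welch"` (default) or `"student"`.
#' @param radius Smoothing window radius in probes (default 3).
#' @param flank_bp Flank width used when mapping probes to islands.
#' @return A tibble of per-probe rows sorted by `(chromosome, position)`
#'   with columns `probe_id`, `chromosome`, `position`, `island_relation`,
#'   `island_id`, `mean_beta_cases`, `mean_beta_controls`, `delta_beta`,
#'   `t_stat`, `p_nominal`, `p_bonferroni`, `neglog10_p`,
#'   `neglog10_p_smoothed`, `n_cases_used`, `n_controls_used`, `tested`.
#'   The number of tested probes is attached as attribute `m_tests`.
#' @export
run_ewas <- function(bm, manifest, islands = NULL,
                     variant = c("welch", "student"), radius = 3,
                     flank_bp = 250) {
  manifest <- probe_manifest(manifest)
  if (!"island_relation" %in% names(manifest)) {
    if (!is.null(islands)) {
      manifest <- map_probes_to_islands(manifest, islands, flank_bp)
    } else {
      manifest$island_relation <- NA_character_
      manifest$island_id <- NA_character_
    }
  }
  missing_probes <- setdiff(rownames(bm$values), manifest$probe_id)
  if (length(missing_probes) > 0)
    stop(sprintf("probes absent from manifest: %s%s",
                 paste(utils::head(missing_probes, 3), collapse = ", "),
                 if (length(missing_probes) > 3) ", ..." else ""),
         call. = FALSE)

  manifest <- manifest[match(rownames(bm$values), manifest$probe_id), ]
  ord <- order(manifest$chromosome, manifest$position)
  manifest <- manifest[ord, ]
  values <- bm$values[ord, , drop = FALSE]

  res <- .row_t_test(values, case_idx(bm), control_idx(bm),
                     match.arg(variant))
  m_tests <- sum(res$testable)
  if (m_tests == 0) stop("no testable probes", call. = FALSE)

  rows <- tibble::tibble(
    probe_id = manifest$probe_id,
    chromosome = manifest$chromosome,
    position = manifest$position,
    island_relation = manifest$island_relation,
    island_id = manifest$island_id,
    mean_beta_cases = ifelse(res$n_1 > 0, res$mean_1, NA_real_),
    mean_beta_controls = ifelse(res$n_2 > 0, res$mean_2, NA_real_),
    delta_beta = ifelse(res$n_1 > 0 & res$n_2 > 0,
                        res$mean_1 - res$mean_2, NA_real_),
    t_stat = res$t_stat,
    p_nominal = res$p_nominal,
    p_bonferroni = bonferroni(res$p_nominal, m_tests),
    neglog10_p = -log10(res$p_nominal),
    n_cases_used = res$n_1,
    n_controls_used = res$n_2,
    tested = res$testable)

  rows <- smooth_p(rows, radius)
  rows <- rows[, c("probe_id", "chromosome", "position", "island_relation",
                   "island_id", "mean_beta_cases", "mean_beta_controls",
                   "delta_beta", "t_stat", "p_nominal", "p_bonferroni",
                   "neglog10_p", "neglog10_p_smoothed", "n_cases_used",
                   "n_controls_used", "tested")]
  attr(rows, "m_tests") <- m_tests
  rows
}

#' Epi-Manhattan export of an EWAS table
#'
#' @param ewas Output of [run_ewas()].
#' @param highlight_threshold Nominal P below which a probe is flagged
#'   (default `1e-100`, the threshold line drawn in the study's
#'   epi-Manhattan plots).
#' @return Tibble with `chromosome`, `position`, `neglog10_p`, `highlight`.
#' @export
manhattan_table <- function(ewas, highlight_threshold = 1e-100) {
  tibble::tibble(
    chromosome = ewas$chromosome,
    position = ewas$position,
    neglog10_p = ewas$neglog10_p,
    highlight = !is.na(ewas$p_nominal) &
      ewas$p_nominal < highlight_threshold)
}

#' Write an EWAS table
#'
#' @param ewas Output of [run_ewas()].
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @param genome_build Build label for the header comment.
#' @return `ewas`, invisibly.
#' @export
write_ewas <- function(ewas, path, format = c("tsv", "csv"),
                       genome_build = "GRCh37") {
  sep <- .delim_char(format)
  con <- file(path, "w")
  writeLines(.version_header(genome_build), con)
  utils::write.table(as.data.frame(ewas), con, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  invisible(ewas)
}

#' @rdname write_ewas
#' @export
read_ewas <- function(path, format = c("tsv", "csv")) {
  sep <- .delim_char(format)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  tibble::as_tibble(tab)
}
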