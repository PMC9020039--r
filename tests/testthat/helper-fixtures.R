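# Shared fixtures and independent brute-force oracles.

# Beta matrix with explicit values: `cases` and `controls` are
# probes x n matrices (or vectors recycled per probe).
make_bm <- function(cases, controls, probe_ids = NULL) {
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  stopifnot(nrow(cases) == nrow(controls))
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%05d", seq_len(nrow(cases)))
  values <- cbind(cases, controls)
  rownames(values) <- probe_ids
  colnames(values) <- c(sprintf("case_%02d", seq_len(ncol(cases))),
                        sprintf("ctrl_%02d", seq_len(ncol(controls))))
  meta <- data.frame(
    sample_id = colnames(values),
    group = rep(c("case", "control"), c(ncol(cases), ncol(controls))))
  beta_matrix(values, meta)
}

# Straight-line per-chromosome windowed mean of -log10 P, O(n * r) loops;
# deliberately naive so it stays independent of the package's cumsum path.
brute_smooth <- function(neglog10_p, chromosome, radius) {
  n <- length(neglog10_p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq(i - radius, i + radius)) {
      if (j >= 1 && j <= n && chromosome[j] == chromosome[i])
        acc <- c(acc, neglog10_p[j])
    }
    out[i] <- mean(acc, na.rm = TRUE)
  }
  out
}

# Exhaustive evaluation of the five assignment criteria for one query's
# records (already joined with subject metadata). Returns the assigned
# gene or NA; loops over candidates rather than sorting.
brute_assign_gene <- function(recs) {
  cand <- recs[recs$biotype == "protein_coding", , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, ]
    if (is.null(best)) { best <- r; next }
    if (r$alignment_length > best$alignment_length ||
        (r$alignment_length == best$alignment_length &&
         (r$bit_score > best$bit_score ||
          (r$bit_score == best$bit_score &&
           (r$e_value < best$e_value ||
            (r$e_value == best$e_value && r$subject_id < best$subject_id))))))
      best <- r
  }
  ok <- best$subject_length == best$alignment_length &&
    best$alignment_length > 300 && best$mismatches < 4 &&
    best$gap_openings <= 1
  if (ok) best$gene else NA_character_
}

# Signature rows of one island, shaped like run_ewas() output.
signature_island_rows <- function(island) {
  sig <- epicblc_signature()
  sig[sig$island_id == island, ]
}
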