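#' Read a 12-column BLAST tabular hits file (outfmt 6 style)
#'
#' Columns: query id, subject id, percent identity, alignment length,
#' mismatches, gap openings, query start/end, subject start/end, e-value,
#' bit score.
#'
#' @param path Path to the tab-delimited hits file (no header).
#' @return Tibble with columns `query_id`, `subject_id`, `pident`,
#'   `alignment_length`, `mismatches`, `gap_openings`, `qstart`, `qend`,
#'   `sstart`, `send`, `e_value`, `bit_score`.
#' @export
read_blast_tabular <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) != 12)
    stop("expected 12 tab-separated columns of BLAST tabular output",
         call. = FALSE)
  names(tab) <- c("query_id", "subject_id", "pident", "alignment_length",
                  "mismatches", "gap_openings", "qstart", "qend", "sstart",
                  "send", "e_value", "bit_score")
  tibble::as_tibble(tab)
}

#' Read a cDNA metadata table
#'
#' @param path Delimited text with columns `subject_id`, `gene`, `biotype`
#'   and `subject_length` (or `length`).
#' @param format `"tsv"` or `"csv"`.
#' @return Tibble with those columns.
#' @export
read_cdna_metadata <- function(path, format = c("tsv", "csv")) {
  sep <- .delim_char(format)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if ("length" %in% names(tab) && !"subject_length" %in% names(tab))
    names(tab)[names(tab) == "length"] <- "subject_length"
  req <- c("subject_id", "gene", "biotype", "subject_length")
  if (!all(req %in% names(tab)))
    stop("cDNA metadata needs columns subject_id, gene, biotype, length",
         call. = FALSE)
  tibble::as_tibble(tab)
}

#' Assign one reconstructed transcript to a known gene
#'
#' Implements the five-criterion assignment rule for de novo reconstructed
#' transcripts aligned against a cDNA database:
#' (i) only protein-coding subjects are candidates;
#' (ii) among candidates, the hit with the highest alignment length is
#' selected (ties broken by higher bit score, then lower e-value, then
#' lexicographic subject id);
#' (iii) the selected hit must cover its subject end to end
#' (`subject_length == alignment_length`) and be longer than 300 nt
#' (strict);
#' (iv) fewer than 4 mismatches;
#' (v) at most one gap opening.
#' The transcript is assigned to the selected subject's gene only when all
#' criteria hold; otherwise the failing criteria are flagged.
#'
#' @param records Data frame of alignment records for a single query,
#'   already joined with subject metadata: columns `query_id`,
#'   `subject_id`, `gene`, `biotype`, `subject_length`,
#'   `alignment_length`, `mismatches`, `gap_openings`, `e_value`,
#'   `bit_score`. May be empty.
#' @return One-row tibble: `query_id`, `assigned_gene` (`NA` when
#'   unassigned), `subject_id` of the selected candidate (`NA` when no
#'   candidate survives the biotype filter) and logical flags `pass_i` ..
#'   `pass_v`.
#' @export
assign_transcript <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0 && length(unique(records$query_id)) != 1)
    stop("records must all share one query_id", call. = FALSE)
  query <- if (nrow(records) > 0) records$query_id[1] else NA_character_

  unassigned <- function(pass_i, winner = NA_character_,
                         pass_iii = NA, pass_iv = NA, pass_v = NA) {
    tibble::tibble(query_id = query, assigned_gene = NA_character_,
                   subject_id = winner, pass_i = pass_i,
                   pass_ii = pass_i, pass_iii = pass_iii,
                   pass_iv = pass_iv, pass_v = pass_v)
  }
  if (nrow(records) == 0) return(unassigned(pass_i = FALSE))

  candidates <- records[records$biotype == "protein_coding", ]
  if (nrow(candidates) == 0) return(unassigned(pass_i = FALSE))

  ord <- order(-candidates$alignment_length, -candidates$bit_score,
               candidates$e_value, candidates$subject_id)
  win <- candidates[ord[1], ]

  pass_iii <- win$subject_length == win$alignment_length &&
    win$alignment_length > 300
  pass_iv <- win$mismatches < 4
  pass_v <- win$gap_openings <= 1
  assigned <- pass_iii && pass_iv && pass_v

  tibble::tibble(
    query_id = query,
    assigned_gene = if (assigned) win$gene else NA_character_,
    subject_id = win$subject_id,
    pass_i = TRUE, pass_ii = TRUE,
    pass_iii = pass_iii, pass_iv = pass_iv, pass_v = pass_v)
}

#' Assign every query in a hits table
#'
#' Joins BLAST-tabular hits with cDNA metadata and applies
#' [assign_transcript()] per query.
#'
#' @param hits Tibble as from [read_blast_tabular()] or
#'   [simulate_alignment_records()].
#' @param cdna Subject metadata tibble (`subject_id`, `gene`, `biotype`,
#'   `subject_length`).
#' @return Tibble with one assignment row per query.
#' @export
assign_transcripts <- function(hits, cdna) {
  hits <- tibble::as_tibble(hits)
  unknown <- setdiff(hits$subject_id, cdna$subject_id)
  if (length(unknown) > 0)
    stop(sprintf("hits reference subjects absent from cDNA metadata: %s",
                 paste(utils::head(unknown, 3), collapse = ", ")),
         call. = FALSE)
  j <- match(hits$subject_id, cdna$subject_id)
  hits$gene <- cdna$gene[j]
  hits$biotype <- cdna$biotype[j]
  hits$subject_length <- cdna$subject_length[j]
  out <- lapply(split(hits, hits$query_id), assign_transcript)
  out <- do.call(rbind, out)
  tibble::as_tibble(out[order(out$query_id), ])
}

#' Aggregate transcript abundances to gene level
#'
#' Gene TPM is the sum of the TPM of the transcripts assigned to it;
#' transcripts without an assignment are pooled under `"unassigned"`, so
#' total TPM is conserved.
#'
#' @param abundance Tibble with columns `target_id` (transcript) and `tpm`
#'   (non-negative).
#' @param assignments Output of [assign_transcripts()].
#' @return Tibble `(gene, tpm)` sorted by decreasing TPM, `"unassigned"`
#'   last.
#' @export
aggregate_gene_expression <- function(abundance, assignments) {
  abundance <- tibble::as_tibble(abundance)
  if (any(abundance$tpm < 0)) stop("TPM must be >= 0", call. = FALSE)
  gene <- assignments$assigned_gene[match(abundance$target_id,
                                          assignments$query_id)]
  gene[is.na(gene)] <- "unassigned"
  agg <- stats::aggregate(list(tpm = abundance$tpm), list(gene = gene), sum)
  agg <- agg[order(agg$gene == "unassigned", -agg$tpm), ]
  tibble::as_tibble(agg)
}

#' Relative expression from qPCR quantification cycles
#'
#' Comparative Cq (delta-delta-Cq) with multiple reference genes: per
#' sample, `dCq = Cq_target - mean(Cq_references)` (the arithmetic mean of
#' reference Cq values corresponds to the geometric mean of reference
#' quantities); the fold change of a sample relative to the calibrator
#' group is `efficiency^-(dCq - mean(dCq_calibrator))`. By construction
#' the calibrator group's geometric-mean fold change is 1, and adding a
#' constant to every Cq of a sample (a plate offset) leaves fold changes
#' unchanged.
#'
#' @param cq Tibble with columns `sample`, `group`, `gene`, `cq`.
#' @param targets Target gene names.
#' @param references Reference gene names (default `GAPDH` and `TBP`).
#' @param calibrator Group label used as the calibrator (fold change 1).
#' @param efficiency Amplification efficiency (default 2: one cycle = one
#'   doubling).
#' @return Tibble `(sample, group, gene, dcq, fold_change)` for every
#'   target gene and sample.
#' @export
relative_expression <- function(cq, targets, references = c("GAPDH", "TBP"),
                                calibrator = "control", efficiency = 2) {
  cq <- tibble::as_tibble(cq)
  req <- c("sample", "group", "gene", "cq")
  if (!all(req %in% names(cq)))
    stop("cq table needs columns sample, group, gene, cq", call. = FALSE)
  if (!calibrator %in% cq$group)
    stop(sprintf("no samples in calibrator group '%s'", calibrator),
         call. = FALSE)

  samples <- unique(cq$sample)
  ref_mean <- vapply(samples, function(s) {
    r <- cq$cq[cq$sample == s & cq$gene %in% references]
    if (length(r) != length(references) || anyNA(r))
      stop(sprintf("sample '%s' is missing a reference Cq", s),
           call. = FALSE)
    mean(r)
  }, numeric(1))

  out <- list()
  for (g in targets) {
    sub <- cq[cq$gene == g, ]
    if (!all(samples %in% sub$sample))
      stop(sprintf("missing Cq for target '%s' in some samples", g),
           call. = FALSE)
    dcq <- sub$cq - unname(ref_mean[match(sub$sample, samples)])
    cal <- mean(dcq[sub$group == calibrator])
    out[[g]] <- tibble::tibble(
      sample = sub$sample, group = sub$group, gene = g, dcq = dcq,
      fold_change = efficiency^-(dcq - cal))
  }
  do.call(rbind, out)
}
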