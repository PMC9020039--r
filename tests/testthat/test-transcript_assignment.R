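rec <- function(query = "q1", subject = "s1", gene = "GENE01",
                biotype = "protein_coding", alen = 350, slen = 350,
                mism = 3, gaps = 1, evalue = 1e-50, bits = 700) {
  tibble::tibble(query_id = query, subject_id = subject, gene = gene,
                 biotype = biotype, alignment_length = alen,
                 subject_length = slen, mismatches = mism,
                 gap_openings = gaps, e_value = evalue, bit_score = bits)
}

test_that("the five assignment criteria pass and fail at their printed bounds", {
  # all bounds exactly satisfied: 350 nt full-length, 3 mismatches, 1 gap
  full <- assign_transcript(rec())
  expect_equal(full$assigned_gene, "GENE01")
  expect_true(all(unlist(full[, c("pass_i", "pass_ii", "pass_iii",
                                  "pass_iv", "pass_v")])))

  # mismatches must stay strictly below 4
  m4 <- assign_transcript(rec(mism = 4))
  expect_true(is.na(m4$assigned_gene))
  expect_false(m4$pass_iv)
  expect_true(m4$pass_iii && m4$pass_v)

  # subject length must exceed 300 nt, strictly
  s300 <- assign_transcript(rec(alen = 300, slen = 300))
  expect_true(is.na(s300$assigned_gene))
  expect_false(s300$pass_iii)

  # alignment must cover the whole subject
  partial <- assign_transcript(rec(alen = 340, slen = 350))
  expect_false(partial$pass_iii)

  # at most one gap opening
  g2 <- assign_transcript(rec(gaps = 2))
  expect_false(g2$pass_v)

  # non-coding subjects are never candidates
  nc <- assign_transcript(rec(biotype = "lincRNA"))
  expect_true(is.na(nc$assigned_gene))
  expect_false(nc$pass_i)

  # empty record list
  none <- assign_transcript(rec()[0, ])
  expect_true(is.na(none$assigned_gene))

  expect_error(assign_transcript(rbind(rec(query = "a"), rec(query = "b"))),
               "query_id")
})

test_that("candidate selection takes the longest alignment with a stable tie-break", {
  a <- rec(subject = "sA", gene = "GENE01", alen = 400, slen = 400)
  b <- rec(subject = "sB", gene = "GENE02", alen = 500, slen = 500)
  expect_equal(assign_transcript(rbind(a, b))$assigned_gene, "GENE02")

  # equal lengths: higher bit score, then lower e-value, then subject id
  t1 <- rec(subject = "sA", gene = "GENE01", bits = 900)
  t2 <- rec(subject = "sB", gene = "GENE02", bits = 800)
  expect_equal(assign_transcript(rbind(t2, t1))$subject_id, "sA")
  t3 <- rec(subject = "sC", gene = "GENE03", bits = 900, evalue = 1e-60)
  expect_equal(assign_transcript(rbind(t1, t3))$subject_id, "sC")
  t4 <- rec(subject = "sD", gene = "GENE04", bits = 900, evalue = 1e-60)
  expect_equal(assign_transcript(rbind(t4, t3))$subject_id, "sC")

  # the filter is order-invariant and idempotent
  set.seed(9)
  recs <- rbind(a, b, t1, t2, t3)
  base <- assign_transcript(recs)
  for (i in 1:5) expect_equal(assign_transcript(recs[sample(nrow(recs)), ]),
                              base)

  # a longer non-coding hit never outcompetes coding candidates
  decoy <- rec(subject = "sZ", gene = "GENE09", biotype = "lincRNA",
               alen = 900, slen = 900)
  expect_equal(assign_transcript(rbind(a, decoy))$assigned_gene, "GENE01")
})

test_that("BLAST tabular and cDNA metadata files load and assign end to end", {
  hits_path <- tempfile()
  writeLines(c(
    "q1\ts1\t99.1\t350\t3\t1\t1\t350\t1\t350\t1e-100\t650",
    "q2\ts2\t98.0\t280\t2\t0\t1\t280\t1\t280\t1e-80\t500"),
    hits_path)
  cdna_path <- tempfile()
  writeLines(c("subject_id\tgene\tbiotype\tlength",
               "s1\tTESK2\tprotein_coding\t350",
               "s2\tMMACHC\tprotein_coding\t280"), cdna_path)
  hits <- read_blast_tabular(hits_path)
  expect_equal(nrow(hits), 2)
  cdna <- read_cdna_metadata(cdna_path)
  asg <- assign_transcripts(hits, cdna)
  expect_equal(asg$assigned_gene[asg$query_id == "q1"], "TESK2")
  expect_true(is.na(asg$assigned_gene[asg$query_id == "q2"]))  # 280 <= 300

  bad <- hits; bad$subject_id[1] <- "sX"
  expect_error(assign_transcripts(bad, cdna), "absent from cDNA")
})

test_that("gene-level TPM aggregation is additive and conserves total mass", {
  asg <- tibble::tibble(query_id = c("t1", "t2", "t3"),
                        assigned_gene = c("MMACHC", "MMACHC", NA))
  ab <- tibble::tibble(target_id = c("t1", "t2", "t3"),
                       tpm = c(3, 7, 2))
  gx <- aggregate_gene_expression(ab, asg)
  expect_equal(gx$tpm[gx$gene == "MMACHC"], 10)
  expect_equal(gx$tpm[gx$gene == "unassigned"], 2)

  # no assignments at all: everything lands in "unassigned"
  gx0 <- aggregate_gene_expression(ab, asg[0, ])
  expect_equal(gx0$gene, "unassigned")
  expect_equal(gx0$tpm, 12)

  # conservation on random data
  set.seed(77)
  fix <- simulate_alignment_records(80, 0.6, seed = 14)
  asg2 <- assign_transcripts(fix$hits, fix$cdna)
  ab2 <- tibble::tibble(target_id = fix$truth$query_id,
                        tpm = rexp(nrow(fix$truth), 1 / 50))
  gx2 <- aggregate_gene_expression(ab2, asg2)
  expect_equal(sum(gx2$tpm), sum(ab2$tpm))
  expect_error(aggregate_gene_expression(transform(ab, tpm = -1), asg),
               "TPM")
})

make_cq <- function(dcq_shift = 0) {
  # two controls (calibrator) and one case; references GAPDH + TBP
  samples <- c("ctrl1", "ctrl2", "case1")
  groups <- c("control", "control", "case")
  rows <- list()
  for (i in seq_along(samples)) {
    shift <- if (groups[i] == "case") dcq_shift else 0
    rows[[i]] <- tibble::tibble(
      sample = samples[i], group = groups[i],
      gene = c("GAPDH", "TBP", "MMACHC"),
      cq = c(18, 24, 26 + shift))
  }
  do.call(rbind, rows)
}

test_that("relative expression doubles per cycle and is 1 at the calibrator", {
  # target Cq one cycle lower than calibrator: fold change 2
  up <- relative_expression(make_cq(-1), "MMACHC")
  expect_equal(up$fold_change[up$group == "case"], 2)
  # identical Cq everywhere: fold change 1
  flat <- relative_expression(make_cq(0), "MMACHC")
  expect_equal(flat$fold_change, rep(1, 3))
  # calibrator samples are 1 by construction whenever they agree
  expect_equal(up$fold_change[up$group == "control"], c(1, 1))

  # plate offset: adding a constant to every Cq of a sample changes nothing
  cq <- make_cq(-2.5)
  shifted <- cq
  shifted$cq[shifted$sample == "case1"] <-
    shifted$cq[shifted$sample == "case1"] + 3.7
  expect_equal(relative_expression(shifted, "MMACHC")$fold_change,
               relative_expression(cq, "MMACHC")$fold_change)

  expect_error(relative_expression(cq[cq$gene != "TBP", ], "MMACHC"),
               "reference")
  expect_error(relative_expression(cq, "MMACHC", calibrator = "nope"),
               "calibrator")
})

test_that("relative expression matches a spreadsheet-style recomputation", {
  set.seed(88)
  samples <- sprintf("s%d", 1:6)
  groups <- rep(c("control", "case"), each = 3)
  genes <- c("GAPDH", "TBP", "MMACHC", "TESK2")
  cq <- expand.grid(sample = samples, gene = genes,
                    stringsAsFactors = FALSE)
  cq$group <- groups[match(cq$sample, samples)]
  cq$cq <- runif(nrow(cq), 15, 35)
  res <- relative_expression(cq, c("MMACHC", "TESK2"))

  for (g in c("MMACHC", "TESK2")) {
    for (s in samples) {
      dcq <- cq$cq[cq$sample == s & cq$gene == g] -
        (cq$cq[cq$sample == s & cq$gene == "GAPDH"] +
           cq$cq[cq$sample == s & cq$gene == "TBP"]) / 2
      cal_dcq <- mean(sapply(samples[groups == "control"], function(cs)
        cq$cq[cq$sample == cs & cq$gene == g] -
          (cq$cq[cq$sample == cs & cq$gene == "GAPDH"] +
             cq$cq[cq$sample == cs & cq$gene == "TBP"]) / 2))
      expected <- 2^-(dcq - cal_dcq)
      got <- res$fold_change[res$sample == s & res$gene == g]
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})
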