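#' Simulation configuration for a case-control methylome
#'
#' Defaults mirror the design of the epimutation study the package is built
#' around: 17 cases against 350 controls, promoter CpG islands of seven
#' probes with six adjacent flank probes, and an epimutated island whose
#' probes are hemimethylated in cases (target mean beta 0.45) while fully
#' unmethylated in controls (mean 0.03). Background (open-sea) probes share
#' one distribution across groups, drawn from a realistic mixture of
#' constitutive states. Beta values are drawn from a Beta distribution
#' parameterized by mean `mu` and concentration `phi`
#' (`shape1 = mu * phi`, `shape2 = (1 - mu) * phi`), so all draws live in
#' `[0, 1]` without clipping; `phi = 200` gives a standard deviation of
#' about 0.015 at unmethylated probes and 0.035 at hemimethylated probes.
#'
#' @param n_cases,n_controls Sample sizes (defaults 17 and 350).
#' @param n_probes Total probe count, islands and flanks included.
#' @param islands Data frame with columns `island_id`, `n_probes_in_island`,
#'   `n_flank_probes` describing the islands to lay out.
#' @param epimutated_island_ids Islands whose probes (flanks included) carry
#'   the case-specific methylation gain.
#' @param case_effect Target mean beta at epimutated probes in cases.
#' @param control_level Target mean beta at those probes in controls.
#' @param background_props Named proportions of open-sea probes in each
#'   constitutive state (`fully_unmethylated`, `hemimethylated`,
#'   `fully_methylated`).
#' @param background_means Mean beta of each constitutive state.
#' @param noise_concentration Beta-distribution concentration `phi` (> 0).
#' @param sex_effect_probes Number of open-sea probes whose mean differs by
#'   sex only (0 by default; used to emulate sex-driven PCA structure).
#' @param sex_effect_delta Mean beta shift in males at those probes.
#' @param n_chromosomes Number of chromosomes to spread probes over.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 17,
                       n_controls = 350,
                       n_probes = 2000,
                       islands = data.frame(
                         island_id = sprintf("CpG:%d", 1:5),
                         n_probes_in_island = 7,
                         n_flank_probes = 6),
                       epimutated_island_ids = "CpG:1",
                       case_effect = 0.45,
                       control_level = 0.03,
                       background_props = c(fully_unmethylated = 0.55,
                                            hemimethylated = 0.15,
                                            fully_methylated = 0.30),
                       background_means = c(fully_unmethylated = 0.05,
                                            hemimethylated = 0.50,
                                            fully_methylated = 0.90),
                       noise_concentration = 200,
                       sex_effect_probes = 0,
                       sex_effect_delta = 0.20,
                       n_chromosomes = 1,
                       seed = 1L) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls, n_probes = n_probes,
              islands = tibble::as_tibble(islands),
              epimutated_island_ids = epimutated_island_ids,
              case_effect = case_effect, control_level = control_level,
              background_props = background_props,
              background_means = background_means,
              noise_concentration = noise_concentration,
              sex_effect_probes = sex_effect_probes,
              sex_effect_delta = sex_effect_delta,
              n_chromosomes = n_chromosomes, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 1, cfg$n_controls >= 1, cfg$n_probes >= 1,
            cfg$noise_concentration > 0, cfg$n_chromosomes >= 1)
  if (cfg$case_effect < 0 || cfg$case_effect > 1 ||
      cfg$control_level < 0 || cfg$control_level > 1)
    stop("case_effect and control_level must lie in [0,1]", call. = FALSE)
  if (!all(cfg$epimutated_island_ids %in% cfg$islands$island_id))
    stop("epimutated_island_ids must be a subset of islands$island_id",
         call. = FALSE)
  n_structured <- sum(cfg$islands$n_probes_in_island +
                        cfg$islands$n_flank_probes)
  if (n_structured > cfg$n_probes)
    stop("n_probes smaller than the probes required by the island layout",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Draws one beta value per (probe, sample) pair with per-cell mean mu.
# Errors rather than clipping when the mean/concentration pair is
# unrepresentable (mu of exactly 0 or 1 gives a zero shape parameter).
.draw_beta <- function(mu, phi) {
  shape1 <- mu * phi
  shape2 <- (1 - mu) * phi
  if (any(shape1 <= 0) || any(shape2 <= 0))
    stop("impossible mean/concentration combination: mean must be in (0,1)",
         call. = FALSE)
  matrix(stats::rbeta(length(mu), shape1, shape2), nrow = nrow(mu))
}

#' Simulate a case-control methylome with ground truth
#'
#' Lays out the configured islands (with flank probes on both sides) and
#' open-sea background probes at strictly increasing positions, then draws
#' beta values per probe and sample. At probes of epimutated islands,
#' controls are centered at `control_level` and cases at `case_effect`;
#' all other probes share one distribution across groups (except the
#' optional sex-effect probes, which differ by sex only, in both groups
#' alike). Sexes alternate F/M across samples for exact balance.
#'
#' @param config A [sim_config()].
#' @return A list with elements `beta` ([beta_matrix()]), `manifest`
#'   ([probe_manifest()] with island relations), `islands`
#'   ([cpg_island_set()]), `truth_probes` (per-probe expected state and mean
#'   in each group) and `truth_islands` (per-island epimutated flag).
#' @export
simulate_methylome <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed)

  layout <- .simulate_layout(cfg)
  manifest <- layout$manifest
  islands <- layout$islands

  n_samp <- cfg$n_cases + cfg$n_controls
  sample_meta <- tibble::tibble(
    sample_id = c(sprintf("case_%02d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_controls))),
    group = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
    sex = rep_len(c("F", "M"), n_samp))

  epi <- manifest$island_id %in% cfg$epimutated_island_ids &
    manifest$island_relation != "open_sea"
  mu_control <- ifelse(epi, cfg$control_level,
                       cfg$background_means[layout$background_state])
  mu_case <- ifelse(epi, cfg$case_effect, mu_control)

  mu <- matrix(rep(mu_control, n_samp), nrow = cfg$n_probes)
  mu[, sample_meta$group == "case"] <- mu_case

  if (cfg$sex_effect_probes > 0) {
    open_sea <- which(manifest$island_relation == "open_sea" &
                        !layout$is_sex_probe_candidate_excluded)
    k <- min(cfg$sex_effect_probes, length(open_sea))
    sex_probes <- open_sea[seq_len(k)]
    males <- sample_meta$sex == "M"
    mu[sex_probes, males] <- pmin(0.98, mu[sex_probes, males] +
                                    cfg$sex_effect_delta)
    layout$truth_probes$sex_effect[sex_probes] <- TRUE
  }

  values <- .draw_beta(mu, cfg$noise_concentration)
  dimnames(values) <- list(manifest$probe_id, sample_meta$sample_id)
  bm <- beta_matrix(values, sample_meta)

  truth_probes <- layout$truth_probes
  truth_probes$state_controls <- ifelse(epi, "fully_unmethylated",
                                        layout$background_state)
  truth_probes$state_cases <- ifelse(
    epi, unname(.state_of_mean(cfg$case_effect)), layout$background_state)
  truth_probes$mu_controls <- mu_control
  truth_probes$mu_cases <- mu_case
  truth_probes$epimutated <- epi

  truth_islands <- tibble::tibble(
    island_id = islands$island_id,
    epimutated = islands$island_id %in% cfg$epimutated_island_ids)

  list(beta = bm, manifest = manifest, islands = islands,
       truth_probes = truth_probes, truth_islands = truth_islands)
}

.state_of_mean <- function(mu, low = 0.2, high = 0.6) {
  ifelse(mu < low, "fully_unmethylated",
         ifelse(mu > high, "fully_methylated", "hemimethylated"))
}

# Island/flank/open-sea probe layout at strictly increasing positions.
.simulate_layout <- function(cfg) {
  n_isl <- nrow(cfg$islands)
  chrom_of_island <- rep_len(sprintf("chr%d", seq_len(cfg$n_chromosomes)),
                             n_isl)

  probe_pos <- numeric(0); probe_chr <- character(0)
  probe_rel <- character(0); probe_isl <- character(0)
  isl_start <- isl_end <- numeric(n_isl)

  cursor <- stats::setNames(rep(1e6, cfg$n_chromosomes),
                            sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  for (i in seq_len(n_isl)) {
    chr <- chrom_of_island[i]
    n_in <- cfg$islands$n_probes_in_island[i]
    n_fl <- cfg$islands$n_flank_probes[i]
    start <- cursor[chr]
    in_pos <- start + 10 + 50 * (seq_len(n_in) - 1)
    isl_start[i] <- start
    isl_end[i] <- max(in_pos) + 10
    n_left <- floor(n_fl / 2)
    n_right <- n_fl - n_left
    left_pos <- if (n_left > 0) start - (50 + 55 * (seq_len(n_left) - 1)) else numeric(0)
    right_pos <- if (n_right > 0) isl_end[i] + 50 + 55 * (seq_len(n_right) - 1) else numeric(0)
    pos <- c(sort(left_pos), in_pos, right_pos)
    rel <- c(rep("flank", n_left), rep("in_island", n_in),
             rep("flank", n_right))
    probe_pos <- c(probe_pos, pos)
    probe_chr <- c(probe_chr, rep(chr, length(pos)))
    probe_rel <- c(probe_rel, rel)
    probe_isl <- c(probe_isl, rep(cfg$islands$island_id[i], length(pos)))
    cursor[chr] <- isl_end[i] + 10000
  }

  n_open <- cfg$n_probes - length(probe_pos)
  open_chr <- rep_len(sprintf("chr%d", seq_len(cfg$n_chromosomes)), n_open)
  for (chr in unique(open_chr)) {
    k <- sum(open_chr == chr)
    base <- cursor[chr] + 50000
    pos <- base + 1500 * (seq_len(k) - 1)
    probe_pos <- c(probe_pos, pos)
    probe_chr <- c(probe_chr, rep(chr, k))
    probe_rel <- c(probe_rel, rep("open_sea", k))
    probe_isl <- c(probe_isl, rep(NA_character_, k))
  }

  ord <- order(match(probe_chr, sprintf("chr%d", seq_len(cfg$n_chromosomes))),
               probe_pos)
  probe_chr <- probe_chr[ord]; probe_pos <- probe_pos[ord]
  probe_rel <- probe_rel[ord]; probe_isl <- probe_isl[ord]

  manifest <- probe_manifest(tibble::tibble(
    probe_id = sprintf("cg%07d", seq_along(probe_pos)),
    chromosome = probe_chr, position = probe_pos,
    island_relation = probe_rel, island_id = probe_isl))

  islands <- cpg_island_set(tibble::tibble(
    island_id = cfg$islands$island_id, chromosome = chrom_of_island,
    start = isl_start, end = isl_end))

  n_open_total <- sum(probe_rel == "open_sea")
  states <- names(cfg$background_props)
  counts <- round(cfg$background_props / sum(cfg$background_props) *
                    n_open_total)
  counts[1] <- n_open_total - sum(counts[-1])
  bg_states_pool <- sample(rep(states, counts))
  background_state <- rep(NA_character_, length(probe_rel))
  background_state[probe_rel == "open_sea"] <- bg_states_pool
  # non-open-sea, non-epimutated island probes behave like unmethylated
  # promoter CpGs in both groups
  background_state[probe_rel != "open_sea"] <- "fully_unmethylated"

  truth_probes <- tibble::tibble(
    probe_id = manifest$probe_id, chromosome = probe_chr,
    position = probe_pos, island_id = probe_isl,
    island_relation = probe_rel, sex_effect = FALSE)

  list(manifest = manifest, islands = islands,
       background_state = background_state,
       truth_probes = truth_probes,
       is_sex_probe_candidate_excluded = rep(FALSE, length(probe_rel)))
}

#' Simulate BLAST-tabular alignment fixtures with known assignments
#'
#' Generates alignment records against a small synthetic cDNA database for
#' exercising the transcript-to-gene assignment filter. A configurable
#' fraction of queries satisfy all five assignment criteria; the remaining
#' queries each violate exactly one criterion, cycling through (i) biotype
#' not protein-coding, (ii) a longer-alignment decoy outcompeting a valid
#' hit, (iii) alignment shorter than the subject or subject not longer than
#' 300 nt, (iv) four or more mismatches, (v) more than one gap opening.
#'
#' @param n_transcripts Number of query transcripts.
#' @param fraction_pass Fraction of queries that should be assignable.
#' @param seed Integer seed.
#' @return A list with `hits` (12-column BLAST-outfmt-6-style tibble),
#'   `cdna` (subject metadata: `subject_id`, `gene`, `biotype`,
#'   `subject_length`) and `truth` (per query: `expected_gene`, `violated`).
#' @export
simulate_alignment_records <- function(n_transcripts, fraction_pass = 0.5,
                                       seed = 1L) {
  if (fraction_pass < 0 || fraction_pass > 1)
    stop("fraction_pass must lie in [0,1]", call. = FALSE)
  set.seed(seed)

  genes <- sprintf("GENE%02d", 1:8)
  cdna <- tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(3 * length(genes))),
    gene = rep(genes, each = 3),
    biotype = rep(c("protein_coding", "protein_coding",
                    "processed_pseudogene"), length(genes)),
    subject_length = sample(320:2000, 3 * length(genes), replace = TRUE))
  coding <- cdna[cdna$biotype == "protein_coding", ]
  noncoding <- cdna[cdna$biotype != "protein_coding", ]

  n_pass <- round(n_transcripts * fraction_pass)
  violations <- rep_len(c("i", "ii", "iii", "iv", "v"),
                        n_transcripts - n_pass)

  rows <- list(); truth <- list()
  mk <- function(query, subj, alen, mism, gaps) {
    tibble::tibble(
      query_id = query, subject_id = subj$subject_id,
      pident = round(100 * (1 - mism / alen), 2),
      alignment_length = alen, mismatches = mism, gap_openings = gaps,
      qstart = 1, qend = alen, sstart = 1, send = alen,
      e_value = 10^(-round(stats::runif(1, 50, 180))),
      bit_score = round(2 * alen - 10 * mism + stats::runif(1, 0, 5), 1))
  }
  for (q in seq_len(n_transcripts)) {
    query <- sprintf("TRINITY_DN%04d_c0_g1_i1", q)
    if (q <= n_pass) {
      subj <- coding[sample(nrow(coding), 1), ]
      rows[[length(rows) + 1]] <-
        mk(query, subj, subj$subject_length, sample(0:3, 1), sample(0:1, 1))
      truth[[length(truth) + 1]] <- tibble::tibble(
        query_id = query, expected_gene = subj$gene, violated = NA_character_)
    } else {
      v <- violations[q - n_pass]
      subj <- coding[sample(nrow(coding), 1), ]
      rec <- switch(
        v,
        i = { s <- noncoding[sample(nrow(noncoding), 1), ]
              mk(query, s, s$subject_length, sample(0:3, 1), sample(0:1, 1)) },
        ii = { good <- mk(query, subj, subj$subject_length, sample(0:3, 1),
                          sample(0:1, 1))
               decoy_subj <- coding[sample(nrow(coding), 1), ]
               # longer alignment than any subject, so the decoy wins
               # selection but cannot satisfy subject_length == align_length
               decoy <- mk(query, decoy_subj,
                           max(subj$subject_length,
                               decoy_subj$subject_length) + 100,
                           sample(0:3, 1), sample(0:1, 1))
               rbind(good, decoy) },
        iii = mk(query, subj, max(150, subj$subject_length - 60),
                 sample(0:3, 1), sample(0:1, 1)),
        iv = mk(query, subj, subj$subject_length, sample(4:9, 1),
                sample(0:1, 1)),
        v = mk(query, subj, subj$subject_length, sample(0:3, 1),
               sample(2:4, 1)))
      rows[[length(rows) + 1]] <- rec
      truth[[length(truth) + 1]] <- tibble::tibble(
        query_id = query, expected_gene = NA_character_, violated = v)
    }
  }
  list(hits = do.call(rbind, rows), cdna = cdna, truth = do.call(rbind, truth))
}
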