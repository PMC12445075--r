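# Synthetic multi-omic data with planted ground truth.
#
# One synthetic chromosome ("chrS"), 0-based half-open coordinates. Genes sit
# on a 100-kb grid; every enhancer lives in the intergenic window of a unique
# "home" gene so enhancer intervals never collide. A single global seed fans
# out to fixed per-stage child seeds so each generator is independently
# reproducible.

SEED_OFFSETS <- c(reference = 101L, chip_OSM = 211L, chip_hypoxia = 223L,
                  atac_housekeeping = 301L, atac_inducible = 307L,
                  atac_noninducible = 311L, panel = 401L, bulk = 503L,
                  scrna = 601L)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

child_seed <- function(config, stage) {
  config$seed + unname(SEED_OFFSETS[stage])
}

#' Simulation configuration
#'
#' Parameters of the planted-truth generators. Defaults reproduce the
#' structure of the study the pipeline targets: 14 shared stress-responsive
#' enhancers feeding a 54-gene candidate catalog containing an 18-gene
#' co-expressed module (10 hazardous, 8 protective), a 5 vs 5 cell-line panel
#' with a 93-gene inducibility program, a 177-tumor cohort with hazard ratio 6
#' between activation groups at 40% censoring, and 22,700 single cells in
#' which the high-program state is 62-fold enriched in treated patients.
#'
#' @param seed Global seed; per-stage child seeds are derived by fixed offsets.
#' @param n_genes Size of the bulk/panel gene universe.
#' @param n_enhancers Total enhancer records.
#' @param n_shared_responsive Enhancers differential in both stimulation
#'   conditions (the STAT-open candidates).
#' @param n_condition_private Condition-private differential enhancers, per
#'   condition.
#' @param n_lines_inducible,n_lines_noninducible Cell-line panel group sizes.
#' @param n_lines_extra Additional panel lines with hidden labels, for
#'   classification tests.
#' @param n_tumors Bulk cohort size.
#' @param n_cells Single-cell count.
#' @param n_genes_sc Single-cell gene universe size.
#' @param signature_size Candidate-catalog size: genes reachable from shared
#'   enhancers.
#' @param module_size Size of the planted co-expressed, survival-linked
#'   module within the catalog.
#' @param n_hazardous Hazardous (up in activated tumors) module genes; the
#'   remaining module genes are protective.
#' @param n_inducible_genes Planted up-genes of the cell-line inducibility
#'   program.
#' @param sd_inflate_n Differentially expressed panel genes given inflated
#'   within-group variability (exercises the SD filter).
#' @param effect_log2fc Planted expression shift, log2 units.
#' @param true_hr Hazard ratio of activated vs non-activated tumors.
#' @param censor_frac Expected censored fraction, in \[0, 1).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param treated_enrichment Target fold enrichment of high-program cells in
#'   treated vs naive patients.
#' @param background_peaks Background binding peaks per ChIP condition.
#' @param atac_background Housekeeping accessibility peaks (shared by both
#'   line classes).
#' @param high_mt_frac Fraction of cells forced above the 15% mitochondrial
#'   threshold.
#' @param low_count_frac Fraction of cells forced below the detected-gene
#'   floor.
#' @param sc_min_genes Detected-gene floor used by the synthetic pipeline's
#'   QC stage (the generator's 300-gene universe scales the usual 200 down).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_enhancers = 120L,
                       n_shared_responsive = 14L,
                       n_condition_private = 20L,
                       n_lines_inducible = 5L,
                       n_lines_noninducible = 5L,
                       n_lines_extra = 10L,
                       n_tumors = 177L,
                       n_cells = 22700L,
                       n_genes_sc = 300L,
                       signature_size = 54L,
                       module_size = 18L,
                       n_hazardous = 10L,
                       n_inducible_genes = 93L,
                       sd_inflate_n = 8L,
                       effect_log2fc = 2,
                       true_hr = 6,
                       censor_frac = 0.4,
                       nb_dispersion = 0.03,
                       treated_enrichment = 62,
                       background_peaks = 300L,
                       atac_background = 100L,
                       high_mt_frac = 0.02,
                       low_count_frac = 0.02,
                       sc_min_genes = 100L) {
  cfg <- as.list(environment())
  counts <- c("n_genes", "n_enhancers", "n_shared_responsive",
              "n_condition_private", "n_lines_inducible",
              "n_lines_noninducible", "n_tumors", "n_cells", "n_genes_sc",
              "signature_size", "module_size", "n_hazardous",
              "n_inducible_genes")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      abort(paste0("configuration error: ", f, " must be a positive count"))
    }
  }
  if (cfg$n_shared_responsive > cfg$n_enhancers) {
    abort("configuration error: n_shared_responsive exceeds n_enhancers")
  }
  if (cfg$n_enhancers < cfg$n_shared_responsive + 2 * cfg$n_condition_private) {
    abort("configuration error: n_enhancers too small for private enhancers")
  }
  if (cfg$signature_size > 5 * cfg$n_shared_responsive) {
    abort("configuration error: at most 5 targets per shared enhancer")
  }
  if (cfg$module_size > cfg$signature_size ||
      cfg$n_hazardous > cfg$module_size) {
    abort("configuration error: module sizes inconsistent")
  }
  n_background_enh <- cfg$n_enhancers - cfg$n_shared_responsive -
    2 * cfg$n_condition_private
  needed <- cfg$signature_size + cfg$n_inducible_genes + cfg$sd_inflate_n +
    2 * cfg$n_condition_private + n_background_enh
  if (cfg$n_genes < needed) {
    abort(paste0("configuration error: n_genes must be >= ", needed))
  }
  if (cfg$censor_frac < 0 || cfg$censor_frac >= 1) {
    abort("configuration error: censor_frac must be in [0, 1)")
  }
  if (cfg$true_hr <= 0) abort("configuration error: true_hr must be > 0")
  if (cfg$treated_enrichment <= 0) {
    abort("configuration error: treated_enrichment must be > 0")
  }
  if (cfg$nb_dispersion <= 0) {
    abort("configuration error: nb_dispersion must be > 0")
  }
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate the reference: genes, enhancer map, and ground truth
#'
#' Lays out `n_genes` genes with TSS on a 100-kb grid of one synthetic
#' chromosome and builds a GeneHancer-style enhancer-to-gene map. The
#' `n_shared_responsive` shared enhancers target exactly the
#' `signature_size` candidate genes (1-5 targets each); the first candidate
#' gene plays the role of the integrin locus, with one enhancer centered
#' 13.6 kb upstream of its TSS and a second 51.6 kb downstream.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble: gene, chrom, tss, strand),
#'   `enhancer_map` (tibble: enhancer_id, chrom, start, end, gene,
#'   link_score), and `truth` (planted ground truth; see Details).
#' @details `truth` carries: `shared_enhancer_ids`, `private_enhancer_ids`
#'   (list by condition), `background_enhancer_ids`,
#'   `accessible_in_inducible_ids`, `candidate_genes`, `module_genes`
#'   (list: hazardous, protective), `inducible_genes`, `sd_inflated_genes`,
#'   `enhancers` (interval tibble), and the gene table.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- tibble(
    gene = gene_ids(n),
    chrom = "chrS",
    tss = seq_len(n) * 1e5,
    strand = ifelse(seq_len(n) %% 5 == 0, "-", "+")
  )
  genes$strand[1] <- "+"
  ns <- config$n_shared_responsive
  cand <- genes$gene[seq_len(config$signature_size)]
  base_ind <- config$signature_size
  inducible_genes <- genes$gene[base_ind + seq_len(config$n_inducible_genes)]
  base_sd <- base_ind + config$n_inducible_genes
  sd_genes <- if (config$sd_inflate_n > 0) {
    genes$gene[base_sd + seq_len(config$sd_inflate_n)]
  } else character(0)
  base_priv <- base_sd + config$sd_inflate_n

  # shared enhancers: candidate j targets enhancer ((j-1) mod ns) + 1
  assign_enh <- ((seq_along(cand) - 1) %% ns) + 1
  shared_ids <- sprintf("ENH_S%02d", seq_len(ns))
  enh_w <- 1000
  mid_of <- function(tss, offset) tss + offset
  shared_mid <- vapply(seq_len(ns), function(k) {
    home <- which(assign_enh == k)[1]         # candidate index k
    if (k == 1) mid_of(genes$tss[1], -13600)
    else if (k == 2) mid_of(genes$tss[1], 51600)
    else mid_of(genes$tss[home], -30000)
  }, numeric(1))
  shared_enh <- tibble(
    enhancer_id = shared_ids,
    chrom = "chrS",
    start = shared_mid - enh_w / 2,
    end = shared_mid + enh_w / 2,
    class = "shared"
  )
  shared_links <- tibble(
    enhancer_id = shared_ids[assign_enh],
    gene = cand
  )
  if (ns >= 2) {
    # the downstream intronic enhancer also targets the integrin analog
    shared_links <- bind_rows(shared_links,
                              tibble(enhancer_id = shared_ids[2],
                                     gene = cand[1]))
  }

  one_target_enh <- function(ids, homes, class, offset = -30000) {
    tibble(enhancer_id = ids, chrom = "chrS",
           start = genes$tss[homes] + offset - enh_w / 2,
           end = genes$tss[homes] + offset + enh_w / 2,
           class = class, gene = genes$gene[homes])
  }
  np <- config$n_condition_private
  osm_ids <- sprintf("ENH_PO%02d", seq_len(np))
  hyp_ids <- sprintf("ENH_PH%02d", seq_len(np))
  osm_enh <- one_target_enh(osm_ids, base_priv + seq_len(np), "private_OSM")
  hyp_enh <- one_target_enh(hyp_ids, base_priv + np + seq_len(np),
                            "private_hypoxia")
  nb <- config$n_enhancers - ns - 2 * np
  bg_ids <- if (nb > 0) sprintf("ENH_B%03d", seq_len(nb)) else character(0)
  bg_enh <- if (nb > 0) {
    one_target_enh(bg_ids, base_priv + 2 * np + seq_len(nb), "background")
  } else NULL
  enhancers <- bind_rows(
    select(shared_enh, -dplyr::any_of("gene")),
    select(osm_enh, "enhancer_id", "chrom", "start", "end", "class"),
    select(hyp_enh, "enhancer_id", "chrom", "start", "end", "class"),
    if (!is.null(bg_enh)) select(bg_enh, "enhancer_id", "chrom", "start",
                                 "end", "class")
  )
  links <- bind_rows(
    shared_links,
    select(osm_enh, "enhancer_id", "gene"),
    select(hyp_enh, "enhancer_id", "gene"),
    if (!is.null(bg_enh)) select(bg_enh, "enhancer_id", "gene")
  )
  link_score <- with_seed(child_seed(config, "reference"),
                          round(runif(nrow(links), 0.5, 1), 4))
  enhancer_map <- left_join(links, enhancers, by = "enhancer_id")
  enhancer_map <- mutate(enhancer_map, link_score = link_score)
  enhancer_map <- select(enhancer_map, "enhancer_id", "chrom", "start",
                         "end", "gene", "link_score")

  module <- cand[seq_len(config$module_size)]
  truth <- list(
    shared_enhancer_ids = shared_ids,
    private_enhancer_ids = list(OSM = osm_ids, hypoxia = hyp_ids),
    background_enhancer_ids = bg_ids,
    accessible_in_inducible_ids = shared_ids,
    candidate_genes = cand,
    module_genes = list(
      hazardous = module[seq_len(config$n_hazardous)],
      protective = module[(config$n_hazardous + 1):config$module_size]
    ),
    inducible_genes = inducible_genes,
    sd_inflated_genes = sd_genes,
    enhancers = enhancers,
    genes = genes
  )
  list(genes = genes, enhancer_map = enhancer_map, truth = truth)
}

# background slot midpoints, in windows beyond the gene grid so background
# peaks never touch enhancers; each condition gets its own offset
bg_slot_mid <- function(config, i, offset) {
  (config$n_genes + i) * 1e5 + offset
}

#' Simulate differential ChIP peaks for one condition
#'
#' Plants high-score, small-adjusted-p peaks on every shared-responsive
#' enhancer and every enhancer private to `condition`, plus background peaks
#' at condition-specific loci away from all enhancers (roughly half below the
#' 0.05 adjusted-p threshold, all with scores below the planted peaks).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_reference()].
#' @param condition `"OSM"` or `"hypoxia"`.
#' @return Peak tibble (BED6+2 columns).
#' @export
simulate_chip <- function(config, truth, condition = c("OSM", "hypoxia")) {
  condition <- match.arg(condition)
  enh <- truth$enhancers
  planted_ids <- c(truth$shared_enhancer_ids,
                   truth$private_enhancer_ids[[condition]])
  pe <- enh[match(planted_ids, enh$enhancer_id), ]
  with_seed(child_seed(config, paste0("chip_", condition)), {
    npl <- nrow(pe)
    jit_l <- floor(runif(npl, 0, 200)); jit_r <- floor(runif(npl, 0, 200))
    planted <- new_peaks(
      chrom = pe$chrom, start = pe$start - jit_l, end = pe$end + jit_r,
      name = sprintf("%s_pk%03d", condition, seq_len(npl)),
      score = runif(npl, 60, 100), strand = ".",
      log2fc = stats::rnorm(npl, config$effect_log2fc, 0.3),
      p_adj = runif(npl, 1e-6, 0.01)
    )
    nbg <- config$background_peaks
    bg <- if (nbg > 0) {
      off <- if (condition == "OSM") 10000 else 60000
      mid <- bg_slot_mid(config, seq_len(nbg), off)
      w <- floor(runif(nbg, 300, 600))
      new_peaks(
        chrom = "chrS", start = mid - w, end = mid + w,
        name = sprintf("%s_bg%04d", condition, seq_len(nbg)),
        score = runif(nbg, 1, 50), strand = ".",
        log2fc = stats::rnorm(nbg, 0, 0.3),
        p_adj = ifelse(runif(nbg) < 0.5, runif(nbg, 0, 0.049),
                       runif(nbg, 0.051, 1))
      )
    } else NULL
    arrange(bind_rows(planted, bg), .data$chrom, .data$start, .data$end)
  })
}

#' Simulate accessibility peaks for one cell-line class
#'
#' Inducible lines get accessibility peaks covering every shared-responsive
#' enhancer; non-inducible lines lack them. Both classes share the same
#' seeded housekeeping-accessible background at loci disjoint from all
#' enhancers.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_reference()].
#' @param line_label `"inducible"` or `"non-inducible"`.
#' @return Peak tibble (BED6+2 columns).
#' @export
simulate_atac <- function(config, truth,
                          line_label = c("inducible", "non-inducible")) {
  line_label <- match.arg(line_label)
  nhk <- config$atac_background
  hk <- if (nhk > 0) {
    with_seed(child_seed(config, "atac_housekeeping"), {
      mid <- bg_slot_mid(config, config$background_peaks + seq_len(nhk),
                         10000)
      w <- floor(runif(nhk, 300, 600))
      new_peaks(chrom = "chrS", start = mid - w, end = mid + w,
                name = sprintf("hk_%03d", seq_len(nhk)),
                score = runif(nhk, 10, 60), strand = ".",
                log2fc = 0, p_adj = runif(nhk, 0, 0.05))
    })
  } else NULL
  open <- if (line_label == "inducible") {
    enh <- truth$enhancers
    pe <- enh[match(truth$accessible_in_inducible_ids, enh$enhancer_id), ]
    with_seed(child_seed(config, "atac_inducible"), {
      npl <- nrow(pe)
      jit_l <- floor(runif(npl, 0, 100)); jit_r <- floor(runif(npl, 0, 100))
      new_peaks(chrom = pe$chrom, start = pe$start - jit_l,
                end = pe$end + jit_r,
                name = sprintf("atac_open_%02d", seq_len(npl)),
                score = runif(npl, 60, 100), strand = ".",
                log2fc = stats::rnorm(npl, config$effect_log2fc, 0.3),
                p_adj = runif(npl, 1e-6, 0.01))
    })
  } else NULL
  arrange(bind_rows(open, hk), .data$chrom, .data$start, .data$end)
}

nb_matrix <- function(mu, n_samples, size) {
  m <- matrix(rnbinom(length(mu) * n_samples, mu = rep(mu, n_samples),
                      size = size),
              nrow = length(mu), ncol = n_samples)
  m
}

#' Simulate the cell-line expression panel
#'
#' Negative-binomial counts for the inducible/non-inducible panel plus extra
#' lines with hidden labels. The planted inducibility-program genes are
#' shifted by `effect_log2fc` in every line generated from the inducible
#' process; `sd_inflate_n` of the shifted genes additionally receive strong
#' per-sample multiplicative noise so their within-group log-scale SD exceeds
#' the robustness filter.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_reference()].
#' @return List with `counts` (genes x samples integer matrix) and `labels`
#'   (tibble: sample, group, known).
#' @export
simulate_cellline_panel <- function(config, truth) {
  n_ind <- config$n_lines_inducible
  n_non <- config$n_lines_noninducible
  n_ext <- config$n_lines_extra
  samples <- c(sprintf("IND_%02d", seq_len(n_ind)),
               sprintf("NON_%02d", seq_len(n_non)),
               if (n_ext > 0) sprintf("EXT_%02d", seq_len(n_ext)))
  group <- c(rep("inducible", n_ind), rep("non-inducible", n_non),
             if (n_ext > 0) rep(c("inducible", "non-inducible"),
                                length.out = n_ext))
  known <- c(rep(TRUE, n_ind + n_non), rep(FALSE, n_ext))
  genes <- truth$genes$gene
  planted <- c(truth$inducible_genes, truth$sd_inflated_genes)
  with_seed(child_seed(config, "panel"), {
    mu <- rlnorm(length(genes), log(100), 1)
    mu[match(planted, genes)] <- rlnorm(length(planted), log(300), 0.5)
    mu_mat <- matrix(mu, nrow = length(genes), ncol = length(samples))
    is_ind <- group == "inducible"
    shift <- 2^config$effect_log2fc
    mu_mat[match(planted, genes), is_ind] <-
      mu_mat[match(planted, genes), is_ind] * shift
    sd_idx <- match(truth$sd_inflated_genes, genes)
    if (length(sd_idx) > 0) {
      noise <- matrix(rlnorm(length(sd_idx) * length(samples), 0, 3),
                      nrow = length(sd_idx))
      mu_mat[sd_idx, ] <- mu_mat[sd_idx, ] * noise
    }
    counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                             size = 1 / config$nb_dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, samples))
    list(counts = counts,
         labels = tibble(sample = samples, group = group, known = known))
  })
}

# expected censored fraction P(T > C) for C ~ U(0, tau) against the
# two-group exponential mixture; used to calibrate tau
expected_censored <- function(tau, rates, prob) {
  sum(prob * (1 - exp(-rates * tau)) / (rates * tau))
}

#' Simulate the bulk tumor cohort
#'
#' Each tumor carries a latent activation state `a` (Bernoulli 1/2).
#' Hazardous module genes are up-shifted and protective genes down-shifted by
#' `effect_log2fc` when `a = 1`, which plants the co-expression structure the
#' correlation stage detects. Event times are exponential with rate
#' `lambda0 * true_hr^a`; censoring times are uniform on `(0, tau)` with
#' `tau` calibrated so the expected censored fraction equals `censor_frac`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_reference()].
#' @param lambda0 Baseline event rate (per month); default gives a 24-month
#'   median in the non-activated group.
#' @return List with `expr` (genes x tumors counts), `survival` (tibble:
#'   sample, time, event), `activation` (tibble: sample, activated).
#' @export
simulate_bulk_cohort <- function(config, truth, lambda0 = log(2) / 24) {
  n <- config$n_tumors
  genes <- truth$genes$gene
  haz <- truth$module_genes$hazardous
  prot <- truth$module_genes$protective
  samples <- sprintf("T%03d", seq_len(n))
  with_seed(child_seed(config, "bulk"), {
    a <- rbinom(n, 1, 0.5)
    mu <- rlnorm(length(genes), log(100), 1)
    cand_idx <- match(truth$candidate_genes, genes)
    mu[cand_idx] <- rlnorm(length(cand_idx), log(300), 0.5)
    mu_mat <- matrix(mu, nrow = length(genes), ncol = n)
    shift <- 2^config$effect_log2fc
    mu_mat[match(haz, genes), a == 1] <-
      mu_mat[match(haz, genes), a == 1] * shift
    mu_mat[match(prot, genes), a == 1] <-
      mu_mat[match(prot, genes), a == 1] / shift
    expr <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                           size = 1 / config$nb_dispersion),
                   nrow = length(genes), dimnames = list(genes, samples))
    rates <- lambda0 * config$true_hr^a
    t_event <- rexp(n, rates)
    if (config$censor_frac > 0) {
      rr <- lambda0 * config$true_hr^c(0, 1)
      tau <- uniroot(function(x) {
        expected_censored(x, rr, c(0.5, 0.5)) - config$censor_frac
      }, lower = 1e-6, upper = 1e6)$root
      c_time <- runif(n, 0, tau)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    list(
      expr = expr,
      survival = tibble(sample = samples, time = time, event = event),
      activation = tibble(sample = samples, activated = a)
    )
  })
}

#' Simulate single-cell counts with a planted high-program state
#'
#' Negative-binomial counts over a compact gene universe containing the
#' candidate genes, dedicated mitochondrial and ribosomal genes, and a
#' contiguous background block amplified in malignant cells (for the CNV
#' stage). Among malignant epithelial cells a high-program state (strongly
#' elevated integrin-analog expression plus correlated program genes) occurs
#' with per-treatment probabilities whose ratio equals `treated_enrichment`
#' and whose pooled prevalence is 10%, matching the extreme-decile
#' stratification. A fixed fraction of cells is forced above the 15%
#' mitochondrial threshold and another below the detected-gene floor, so QC
#' gates have planted positives.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_reference()].
#' @return List with `counts` (genes x cells integer matrix), `meta` (tibble:
#'   cell, patient, treatment, cell_type, program, forced_high_mt,
#'   forced_low_count), and `genes` (tibble: gene, chrom, pos, is_mt,
#'   is_ribo).
#' @export
simulate_scrna <- function(config, truth) {
  n <- config$n_cells
  n_mt <- 10L; n_ribo <- 10L
  cand <- truth$candidate_genes
  n_bg <- config$n_genes_sc - length(cand) - n_mt - n_ribo
  if (n_bg < 120) abort("configuration error: n_genes_sc too small")
  gene_names <- c(cand, sprintf("MT-%02d", seq_len(n_mt)),
                  sprintf("RPL%02d", seq_len(n_ribo)),
                  sprintf("SCB%03d", seq_len(n_bg)))
  genes <- tibble(gene = gene_names, chrom = "chrS",
                  pos = seq_along(gene_names) * 1000,
                  is_mt = grepl("^MT-", gene_names),
                  is_ribo = grepl("^RPL", gene_names))
  itgb3 <- cand[1]
  program_genes <- truth$module_genes$hazardous
  amp_start <- length(cand) + n_mt + n_ribo + 11L
  amp_genes <- gene_names[amp_start:(amp_start + 99L)]

  # pooled prevalence slightly above the 10% decile, so the extreme-decile
  # estimator sits inside the planted state and stays unbiased
  q <- 0.11
  e_fold <- config$treated_enrichment
  p_naive <- 2 * q / (1 + e_fold)
  p_treated <- 2 * q * e_fold / (1 + e_fold)
  if (p_treated > 1) abort("treated_enrichment incompatible with 11% pool")

  with_seed(child_seed(config, "scrna"), {
    patient <- sprintf("P%02d", sample.int(12, n, replace = TRUE))
    treatment <- ifelse(as.integer(substring(patient, 2)) <= 6, "naive",
                        "treated")
    r <- runif(n)
    cell_type <- ifelse(r < 0.2, "immune",
                        ifelse(r < 0.28, "epithelial_normal",
                               "epithelial_malignant"))
    malignant <- cell_type == "epithelial_malignant"
    p_state <- ifelse(treatment == "treated", p_treated, p_naive)
    program <- malignant & (runif(n) < p_state)

    mu <- rlnorm(length(gene_names), log(1), 1)
    mu[genes$is_mt] <- 0.4
    mu[genes$is_ribo] <- 1
    mu[gene_names == itgb3] <- 1
    mu_mat <- matrix(mu, nrow = length(gene_names), ncol = n)
    shift <- 2^config$effect_log2fc
    prog_idx <- match(program_genes, gene_names)
    mu_mat[prog_idx, program] <- mu_mat[prog_idx, program] * shift
    mu_mat[gene_names == itgb3, program] <-
      mu_mat[gene_names == itgb3, program] * 2^(config$effect_log2fc + 2)
    amp_idx <- match(amp_genes, gene_names)
    mu_mat[amp_idx, malignant] <- mu_mat[amp_idx, malignant] * 2^0.5
    counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                             size = 1 / config$nb_dispersion),
                     nrow = length(gene_names),
                     dimnames = list(gene_names,
                                     sprintf("cell_%05d", seq_len(n))))

    # force mitochondrial fractions across the 15% gate
    n_hi <- floor(config$high_mt_frac * n)
    hi_mt <- sample.int(n, n_hi)
    mt_idx <- which(genes$is_mt)
    non_mt_tot <- colSums(counts[-mt_idx, , drop = FALSE])
    for (j in hi_mt) {
      target <- ceiling(0.25 / 0.75 * non_mt_tot[j])
      per <- rep(target %/% n_mt, n_mt)
      per[seq_len(target %% n_mt)] <- per[seq_len(target %% n_mt)] + 1
      counts[mt_idx, j] <- per
    }
    mt_frac <- colSums(counts[mt_idx, , drop = FALSE]) / colSums(counts)
    cap <- setdiff(which(mt_frac >= 0.15), hi_mt)
    for (j in cap) {
      counts[mt_idx, j] <- floor(counts[mt_idx, j] * 0.10 / mt_frac[j])
    }
    # force low detected-gene cells (disjoint from the high-MT set)
    n_lo <- floor(config$low_count_frac * n)
    lo <- sample(setdiff(seq_len(n), hi_mt), n_lo)
    if (n_lo > 0) {
      keep <- seq_len(min(60L, nrow(counts)))
      counts[-keep, lo] <- 0L
    }
    forced_hi <- logical(n); forced_hi[hi_mt] <- TRUE
    forced_lo <- logical(n); forced_lo[lo] <- TRUE
    meta <- tibble(cell = colnames(counts), patient = patient,
                   treatment = treatment, cell_type = cell_type,
                   program = program, forced_high_mt = forced_hi,
                   forced_low_count = forced_lo)
    list(counts = counts, meta = meta, genes = genes)
  })
}
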