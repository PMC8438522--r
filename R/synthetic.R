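#' Default cluster shifts of the marker regulators
#'
#' Mean log2 shifts (relative to the panel baseline) that plant the three
#' regulation patterns: pattern 3 has the highest METTL14/ZC3H13 and the
#' lowest KIAA1429/HNRNPA2B1, pattern 2 the reverse, and IGF2BP1, IGF2BP3 and
#' YTHDF1 are lowest in pattern 3.
#'
#' @param effect Magnitude of the shift in log2 units (default 1).
#' @return Tibble with columns `gene`, `cluster`, `shift`.
#' @export
default_regulator_effects <- function(effect = 1) {
  tibble::tribble(
    ~gene,        ~cluster, ~shift,
    "METTL14",    1L,       -1,
    "METTL14",    3L,        1,
    "ZC3H13",     1L,       -1,
    "ZC3H13",     3L,        1,
    "KIAA1429",   2L,        1,
    "KIAA1429",   3L,       -1,
    "HNRNPA2B1",  2L,        1,
    "HNRNPA2B1",  3L,       -1,
    "IGF2BP1",    3L,       -1,
    "IGF2BP3",    3L,       -1,
    "YTHDF1",     3L,       -1
  ) |>
    mutate(shift = .data$shift * effect)
}

#' Default cluster links of the immune signatures
#'
#' Pattern 3 carries elevated Th1 and Th17 helper-cell activity, pattern 2
#' elevated Th2 and depressed Th17 activity.
#'
#' The default shift of 1.5 log2 units keeps the planted activity visible to
#' rank-based scoring even though the (stronger) CEG shifts reshuffle a
#' block of ranks in every cluster.
#'
#' @param effect Magnitude of the shift in log2 units (default 1.5).
#' @return Tibble with columns `signature`, `cluster`, `shift`.
#' @export
default_signature_link <- function(effect = 1.5) {
  tibble::tribble(
    ~signature,   ~cluster, ~shift,
    "Th1 cells",  3L,        1,
    "Th17 cells", 3L,        1,
    "Th2 cells",  2L,        1,
    "Th17 cells", 2L,       -1
  ) |>
    mutate(shift = .data$shift * effect)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the three-pattern design: cluster
#' sizes 157/36/212, marker-regulator shifts of 1 log2 unit, Gaussian noise
#' of 0.5 log2 units, 54 cluster-linked co-expressed genes (CEGs), survival
#' with proportional hazards in the true score (positive `hazard_beta` means
#' high score, better PFS) and immunotherapy response with log-odds
#' decreasing in the score (negative `response_beta` means low score
#' responds).
#'
#' @param n_per_cluster Integer vector of length 3: samples per pattern.
#' @param regulator_effects Tibble (`gene`, `cluster`, `shift`): log2 mean
#'   shifts of panel regulators per cluster.
#' @param n_ceg Number of cluster-linked CEGs.
#' @param ceg_effect Log2 scale of the CEG cluster shifts (cluster 2 low,
#'   1 middle, 3 high); each gene's own shift is `ceg_effect` times a
#'   multiplier drawn in \[0.8, 1.2\]. The default of 2 makes planted CEGs
#'   clear the fold-change-2 rule in every one-vs-rest contrast, including
#'   the attenuated middle-cluster one.
#' @param n_background Number of null background genes.
#' @param noise_sd I.i.d. Gaussian noise standard deviation, log2 units.
#' @param signature_link Tibble (`signature`, `cluster`, `shift`): activity
#'   shifts of signature genes per cluster.
#' @param n_signature_genes Genes per immune signature set.
#' @param hazard_beta Log hazard per standard deviation of the true score,
#'   entering as `exp(-hazard_beta * z)`.
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param censor_rate Target marginal censored fraction in \[0, 1\].
#' @param response_beta Log odds of responder per standard deviation of the
#'   true score.
#' @param response_rate Baseline responder probability at the mean score.
#' @param subtype_c3_prop Probability of immune subtype C3 per cluster.
#' @param stage_effect Log-odds shift of advanced T stage per cluster index
#'   (0 = stage independent of pattern).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_cluster = c(157L, 36L, 212L),
                          regulator_effects = default_regulator_effects(),
                          n_ceg = 54L,
                          ceg_effect = 2,
                          n_background = 500L,
                          noise_sd = 0.5,
                          signature_link = default_signature_link(),
                          n_signature_genes = 12L,
                          hazard_beta = 0.7,
                          baseline_hazard = log(2) / 1000,
                          censor_rate = 0.3,
                          response_beta = -1,
                          response_rate = 0.3,
                          subtype_c3_prop = c(0.6943, 0.3333, 0.8774),
                          stage_effect = 0,
                          seed = 1L) {
  if (length(n_per_cluster) != 3L) {
    abort("the design has three regulation patterns: n_per_cluster must have length 3")
  }
  stopifnot(all(n_per_cluster >= 0), n_ceg >= 0, n_background >= 0,
            noise_sd > 0, censor_rate >= 0, censor_rate <= 1,
            response_rate > 0, response_rate < 1,
            all(subtype_c3_prop >= 0), all(subtype_c3_prop <= 1))
  structure(
    list(n_per_cluster = as.integer(n_per_cluster),
         regulator_effects = regulator_effects,
         n_ceg = as.integer(n_ceg), ceg_effect = ceg_effect,
         n_background = as.integer(n_background), noise_sd = noise_sd,
         signature_link = signature_link,
         n_signature_genes = as.integer(n_signature_genes),
         hazard_beta = hazard_beta, baseline_hazard = baseline_hazard,
         censor_rate = censor_rate, response_beta = response_beta,
         response_rate = response_rate, subtype_c3_prop = subtype_c3_prop,
         stage_effect = stage_effect, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# noiseless per-sample CEG means: gene-specific multiplier x cluster offset
.ceg_means <- function(config, cluster, multipliers) {
  offs <- c(0, -1, 1)[cluster]
  outer(multipliers, offs) # n_ceg x n
}

# censoring rate with P(censored) == censor_rate marginally over sample hazards
.solve_censor_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(log_rc) mean(exp(log_rc) / (exp(log_rc) + rates)) - target
  exp(uniroot(f, lower = log(min(rates)) - 20, upper = log(max(rates)) + 20,
              tol = 1e-12)$root)
}

#' Generate a synthetic tumor cohort with planted ground truth
#'
#' Expression is cluster mean plus configured shifts plus i.i.d. Gaussian
#' noise on the log2 scale. The true score of each sample is the oracle PCA
#' score ([compute_m6ascore()]) of the noiseless CEG means, so pattern 3
#' scores highest and pattern 2 lowest. Progression-free survival is
#' exponential with hazard `exp(-hazard_beta * z)` (z = standardized true
#' score) and independent exponential censoring calibrated to `censor_rate`;
#' the responder label is Bernoulli with logit linear in z.
#'
#' @param config A [cohort_config()].
#' @return List of class `m6a_cohort` with elements `expression` (genes x
#'   samples matrix), `clinical` (tibble), `gene_sets` (tibble of immune
#'   signature sets), `truth` (tibble: `sample_id`, `true_cluster`,
#'   `true_score`) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_cluster = c(30, 20, 30)))
#' table(cohort$truth$true_cluster)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  npc <- config$n_per_cluster
  n <- sum(npc)
  cluster <- rep(1:3, npc)
  ids <- sprintf("S%04d", seq_len(n))

  panel <- m6a_regulators()
  reg_base <- runif(nrow(panel), 4, 10)
  shift_mat <- matrix(0, nrow(panel), 3, dimnames = list(panel$gene, NULL))
  if (nrow(config$regulator_effects)) {
    for (i in seq_len(nrow(config$regulator_effects))) {
      e <- config$regulator_effects[i, ]
      if (e$gene %in% rownames(shift_mat)) {
        shift_mat[e$gene, e$cluster] <- shift_mat[e$gene, e$cluster] + e$shift
      }
    }
  }
  expr_reg <- reg_base + shift_mat[, cluster, drop = FALSE] +
    matrix(rnorm(nrow(panel) * n, sd = config$noise_sd), nrow(panel), n)
  rownames(expr_reg) <- panel$gene

  # cluster-linked CEGs: ordered cluster 2 < cluster 1 < cluster 3
  if (config$n_ceg > 0L) {
    ceg_names <- sprintf("CEG%03d", seq_len(config$n_ceg))
    ceg_base <- runif(config$n_ceg, 4, 10)
    ceg_mult <- runif(config$n_ceg, 0.8, 1.2) * config$ceg_effect
    ceg_mu <- .ceg_means(config, cluster, ceg_mult)
    expr_ceg <- ceg_base + ceg_mu +
      matrix(rnorm(config$n_ceg * n, sd = config$noise_sd), config$n_ceg, n)
    rownames(expr_ceg) <- ceg_names
  } else {
    expr_ceg <- matrix(0, 0L, n)
    ceg_mu <- matrix(0, 0L, n)
  }

  sig_names <- unique(config$signature_link$signature)
  if (!length(sig_names)) sig_names <- c("Th1 cells", "Th2 cells", "Th17 cells")
  sig_gene_names <- list()
  sig_rows <- list()
  for (s in sig_names) {
    gnames <- sprintf("%s.G%02d", gsub("[^A-Za-z0-9]", "", toupper(s)),
                      seq_len(config$n_signature_genes))
    base <- runif(config$n_signature_genes, 4, 10)
    shift <- numeric(3)
    link <- config$signature_link[config$signature_link$signature == s, ]
    if (nrow(link)) shift[link$cluster] <- link$shift
    m <- base + matrix(shift[cluster], config$n_signature_genes, n,
                       byrow = TRUE) +
      matrix(rnorm(config$n_signature_genes * n, sd = config$noise_sd),
             config$n_signature_genes, n)
    rownames(m) <- gnames
    sig_gene_names[[s]] <- gnames
    sig_rows[[s]] <- m
  }

  if (config$n_background > 0L) {
    bg_names <- sprintf("BG%04d", seq_len(config$n_background))
    bg_base <- runif(config$n_background, 2, 10)
    expr_bg <- bg_base +
      matrix(rnorm(config$n_background * n, sd = config$noise_sd),
             config$n_background, n)
    rownames(expr_bg) <- bg_names
  } else {
    expr_bg <- matrix(0, 0L, n)
  }

  expr <- rbind(expr_reg, expr_ceg, do.call(rbind, unname(sig_rows)), expr_bg)
  colnames(expr) <- ids

  # oracle true score: PCA score of the noiseless CEG means
  if (config$n_ceg >= 2L) {
    mu0 <- ceg_mu
    colnames(mu0) <- ids
    rownames(mu0) <- rownames(expr_ceg)
    true_score <- compute_m6ascore(mu0)$score
  } else {
    true_score <- c(0, -1, 1)[cluster]
  }
  z <- if (sd(true_score) > 0) as.numeric(scale(true_score)) else true_score

  rates <- config$baseline_hazard * exp(-config$hazard_beta * z)
  t_event <- rexp(n, rates)
  if (config$censor_rate > 0) {
    rate_c <- .solve_censor_rate(rates, config$censor_rate)
    t_cens <- rexp(n, rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  pfs_time <- pmin(t_event, t_cens)
  pfs_event <- as.integer(t_event <= t_cens)

  p_resp <- plogis(qlogis(config$response_rate) + config$response_beta * z)
  responder <- rbinom(n, 1L, p_resp) == 1L
  response <- character(n)
  response[responder] <- sample(c("CR", "PR"), sum(responder), TRUE,
                                prob = c(0.3, 0.7))
  response[!responder] <- sample(c("SD", "PD"), sum(!responder), TRUE,
                                 prob = c(0.4, 0.6))

  p_adv <- plogis(qlogis(0.4) + config$stage_effect * (cluster - 2))
  subtype <- ifelse(runif(n) < config$subtype_c3_prop[cluster], "C3",
                    sample(c("C1", "C2", "C4"), n, TRUE))
  clinical <- tibble::tibble(
    sample_id = ids,
    pfs_time = pfs_time,
    pfs_event = pfs_event,
    t_stage = ifelse(runif(n) < p_adv, "T3", "T2"),
    n_stage = ifelse(runif(n) < 0.2, "N1", "N0"),
    m_stage = ifelse(runif(n) < 0.03, "M1", "M0"),
    gleason = sample(6:10, n, TRUE, prob = c(0.15, 0.3, 0.3, 0.15, 0.1)),
    psa = round(exp(rnorm(n, log(10), 0.6)), 1),
    immune_subtype = subtype,
    response = response
  )

  gene_sets <- tibble::tibble(
    name = names(sig_gene_names),
    description = "synthetic immune signature",
    genes = unname(sig_gene_names)
  )

  truth <- tibble::tibble(sample_id = ids, true_cluster = cluster,
                          true_score = true_score)
  structure(list(expression = expr, clinical = clinical,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "m6a_cohort")
}

#' @export
print.m6a_cohort <- function(x, ...) {
  cat(sprintf("synthetic m6A cohort: %d samples, %d genes, %d signature sets\n",
              ncol(x$expression), nrow(x$expression), nrow(x$gene_sets)))
  cat("pattern sizes:", paste(table(x$truth$true_cluster), collapse = "/"), "\n")
  invisible(x)
}

#' Generate a cohort with a planted moderator of a regulator-signature link
#'
#' Rebuilds the genes of one immune signature so their level tracks the
#' product of the regulator's (centered) expression and an affine function of
#' the moderator gene's (centered) expression. Within any subsample, the
#' correlation between regulator and signature score then increases (or
#' decreases, per `sign`) with the subsample median of the moderator, which
#' is exactly the structure the resampling co-expression screen targets.
#'
#' @param config A [cohort_config()].
#' @param regulator Regulator gene whose signature link is moderated.
#' @param moderator Name of the planted moderator gene (added to the matrix).
#' @param signature Signature whose genes carry the moderated link.
#' @param strength Moderation strength (0 = no moderation, the null
#'   scenario); 1.5 is the strong preset.
#' @param sign +1 for positive moderation, -1 to flip its direction.
#' @param offset Baseline regulator-signature coupling so the within-replicate
#'   correlation is itself detectable.
#' @param main_effect Direct (moderation-free) effect of the moderator on the
#'   signature genes; keeps the signature elevated under high moderator
#'   within both regulator strata, the pattern a median-split contrast
#'   displays.
#' @param sig_noise_sd Residual noise of the rebuilt signature genes.
#' @return An `m6a_cohort`; `truth` gains a `planted_moderator` attribute
#'   (list with `regulator`, `signature`, `moderator`, `strength`, `sign`).
#' @export
generate_moderator_scenario <- function(config,
                                        regulator = "HNRNPA2B1",
                                        moderator = "MSMB",
                                        signature = "Th1 cells",
                                        strength = 1.5,
                                        sign = 1,
                                        offset = 0.6,
                                        main_effect = strength,
                                        sig_noise_sd = 0.3) {
  cohort <- generate_cohort(config)
  expr <- cohort$expression
  if (!regulator %in% rownames(expr)) abort("regulator not in expression matrix")
  sig_genes <- cohort$gene_sets$genes[[match(signature, cohort$gene_sets$name)]]
  if (is.null(sig_genes)) abort("signature not found in cohort gene sets")
  n <- ncol(expr)

  m_raw <- rnorm(n, 7, 1)
  r_c <- as.numeric(scale(expr[regulator, ]))
  m_c <- as.numeric(scale(m_raw))
  loading <- runif(length(sig_genes), 0.8, 1.2)
  base <- runif(length(sig_genes), 4, 10)
  coupling <- r_c * (offset + sign * strength * m_c) +
    sign * main_effect * m_c
  expr[sig_genes, ] <- base + outer(loading, coupling) +
    matrix(rnorm(length(sig_genes) * n, sd = sig_noise_sd),
           length(sig_genes), n)
  expr <- rbind(expr, matrix(m_raw, 1L, n, dimnames = list(moderator, NULL)))

  cohort$expression <- expr
  attr(cohort$truth, "planted_moderator") <- list(
    regulator = regulator, signature = signature, moderator = moderator,
    strength = strength, sign = sign)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Persists `expression.tsv`, `clinical.csv`, `sets.gmt` and `truth.tsv`
#' plus a JSON manifest with the seed and generator parameters.
#'
#' @param cohort An `m6a_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "sets.gmt"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$regulator_effects <- as.data.frame(cfg$regulator_effects)
  cfg$signature_link <- as.data.frame(cfg$signature_link)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
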