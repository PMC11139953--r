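SIM_CLASSES <- c(
  "stable_housekeeping", "tissue_specific",
  "within_tissue_stable_tissue_variable", "heterogeneous_marker",
  "sex_dimorphic", "silent", "background_noncoding"
)

#' Configuration for the synthetic cohort generator
#'
#' Defines a GTEx-shaped multi-tissue cohort with planted gene classes on
#' the natural TPM scale. Values are drawn log-normally with class-specific
#' location and dispersion; zeros come from per-class dropout. Defaults
#' produce 20 tissues with strongly unbalanced donor counts (400 down to
#' 4 samples, ~1,470 in total) and 2,000 genes:
#'
#' * `stable_housekeeping` - one shared log-mean, small within- and
#'   between-tissue spread: low Gini on both axes.
#' * `tissue_specific` - high expression in one designated tissue,
#'   near-zero (dropout + tiny leak) elsewhere.
#' * `within_tissue_stable_tissue_variable` - tight within every tissue
#'   but with large tissue-to-tissue mean shifts (testis-restricted-like
#'   behaviour: passes the tissue axis, fails the subject axis).
#' * `heterogeneous_marker` - inflated donor-to-donor spread concentrated
#'   in the designated heterogeneous tissue (whole-blood analogue).
#' * `sex_dimorphic` - donor spread multiplied in one sex (male) within the
#'   designated sex tissue (liver analogue).
#' * `silent` - exact zeros everywhere.
#' * `background_noncoding` - non-coding background, mostly zeros with
#'   sporadic tiny values.
#'
#' A per-tissue dispersion multiplier marks one heterogeneous tissue (the
#' largest, multiplier 2.5) and one quiet tissue (the second largest,
#' multiplier 0.2, the cerebellum/testis analogue).
#'
#' @param n_tissues number of tissues.
#' @param samples_per_tissue integer vector of per-tissue donor counts;
#'   default: a geometric-like decay from 400 to 4.
#' @param n_subjects size of the donor pool samples are drawn from.
#' @param male_fraction donor male fraction (GTEx skews male).
#' @param n_stable,n_tissue_specific,n_tissue_variable,n_heterogeneous,n_sex_dimorphic,n_silent,n_noncoding
#'   genes per planted class.
#' @param stable_log_mean,variable_log_mean,hetero_log_mean,sex_log_mean
#'   class baseline log-means (natural log TPM).
#' @param baseline_log_sd gene-to-gene spread of baselines.
#' @param within_sd within-tissue log-sd for the stable and
#'   tissue-variable classes.
#' @param between_sd_stable,between_sd_variable tissue-to-tissue log-sd of
#'   the stable resp. tissue-variable classes.
#' @param specific_log_mean,specific_within_sd expression of
#'   tissue-specific genes in their designated tissue.
#' @param specific_dropout,leak_log_mean,leak_sd off-target behaviour of
#'   tissue-specific genes: probability of an exact zero, and the
#'   log-normal of the tiny leak values.
#' @param hetero_sd,hetero_base_sd,hetero_between_sd heterogeneous-marker
#'   spread in the designated heterogeneous tissue / elsewhere / between
#'   tissues.
#' @param sex_sd_high,sex_sd_low,sex_base_sd sex-dimorphic spread for the
#'   affected (male) and unaffected (female) group in the designated sex
#'   tissue, and elsewhere.
#' @param noncoding_dropout,noncoding_log_mean,noncoding_sd background
#'   non-coding class parameters.
#' @param heterogeneous_tissue,quiet_tissue,sex_tissue designated tissue
#'   indices (1-based into the tissue registry).
#' @param heterogeneous_sd_multiplier,quiet_sd_multiplier per-tissue
#'   dispersion multipliers applied to all within-tissue log-sds.
#' @param seed root seed; fixes the full output bit-for-bit. Per-gene
#'   substreams are derived by stable hashing of the gene id, so adding
#'   genes never perturbs existing ones.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tissues = 20L,
                       samples_per_tissue = NULL,
                       n_subjects = 1000L,
                       male_fraction = 0.67,
                       n_stable = 120L,
                       n_tissue_specific = 60L,
                       n_tissue_variable = 150L,
                       n_heterogeneous = 100L,
                       n_sex_dimorphic = 30L,
                       n_silent = 100L,
                       n_noncoding = 1440L,
                       stable_log_mean = log(50),
                       variable_log_mean = log(20),
                       hetero_log_mean = log(30),
                       sex_log_mean = log(40),
                       baseline_log_sd = 0.8,
                       within_sd = 0.08,
                       between_sd_stable = 0.05,
                       between_sd_variable = 1.5,
                       specific_log_mean = log(200),
                       specific_within_sd = 0.4,
                       specific_dropout = 0.3,
                       leak_log_mean = log(0.02),
                       leak_sd = 0.5,
                       hetero_sd = 1.2,
                       hetero_base_sd = 0.25,
                       hetero_between_sd = 0.1,
                       sex_sd_high = 0.8,
                       sex_sd_low = 0.3,
                       sex_base_sd = 0.2,
                       noncoding_dropout = 0.95,
                       noncoding_log_mean = log(0.3),
                       noncoding_sd = 1,
                       heterogeneous_tissue = 1L,
                       quiet_tissue = 2L,
                       sex_tissue = 3L,
                       heterogeneous_sd_multiplier = 2.5,
                       quiet_sd_multiplier = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$samples_per_tissue)) {
    cfg$samples_per_tissue <- default_tissue_sizes(n_tissues)
  }
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_tissue_sizes <- function(n_tissues) {
  if (n_tissues == 20L) {
    return(c(400L, 200L, 150L, 120L, 100L, 80L, 70L, 60L, 50L, 45L,
             40L, 35L, 30L, 25L, 20L, 15L, 12L, 10L, 6L, 4L))
  }
  pmax(4L, as.integer(round(exp(seq(log(400), log(4), length.out = n_tissues)))))
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_stable, cfg$n_tissue_specific, cfg$n_tissue_variable,
              cfg$n_heterogeneous, cfg$n_sex_dimorphic, cfg$n_silent,
              cfg$n_noncoding)
  if (any(counts < 0)) stop("gene-class counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("no genes configured", call. = FALSE)
  sds <- c(cfg$baseline_log_sd, cfg$within_sd, cfg$between_sd_stable,
           cfg$between_sd_variable, cfg$specific_within_sd, cfg$leak_sd,
           cfg$hetero_sd, cfg$hetero_base_sd, cfg$hetero_between_sd,
           cfg$sex_sd_high, cfg$sex_sd_low, cfg$sex_base_sd, cfg$noncoding_sd)
  if (any(sds < 0)) stop("log-sd parameters must be >= 0", call. = FALSE)
  if (length(cfg$samples_per_tissue) != cfg$n_tissues) {
    stop("samples_per_tissue must have length n_tissues", call. = FALSE)
  }
  if (any(cfg$samples_per_tissue < 1)) {
    stop("each tissue needs at least one sample", call. = FALSE)
  }
  if (max(cfg$samples_per_tissue) > cfg$n_subjects) {
    stop("n_subjects must be at least the largest tissue size", call. = FALSE)
  }
  for (d in c("heterogeneous_tissue", "quiet_tissue", "sex_tissue")) {
    if (cfg[[d]] < 1L || cfg[[d]] > cfg$n_tissues) {
      stop(d, " must index a tissue in 1..n_tissues", call. = FALSE)
    }
  }
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1) {
    stop("male_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (p in c("specific_dropout", "noncoding_dropout")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(cfg)
}

# deterministic per-gene RNG substream: polynomial hash of the gene id
# folded with the root seed, kept below 2^31
substream_seed <- function(root, id) {
  h <- 0
  for (k in utf8ToInt(id)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((h + (as.numeric(root) %% 2147483647) * 7919) %% 2147483647)
}

#' Generate a synthetic multi-tissue cohort with planted gene classes
#'
#' Draws a full cohort (per-tissue expression matrices plus a subject
#' phenotype table), a matching gene catalog, and the truth labels of every
#' planted gene class described in [sim_config()]. The same seed yields a
#' bit-identical cohort; each gene has its own RNG substream derived by
#' stable hashing.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (an `expr_cohort`), `catalog`
#'   (a [gene_catalog()]), `truth` (data frame `gene_id`, `class`,
#'   `designated_tissue`) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  cfg <- config
  nT <- cfg$n_tissues
  sizes <- cfg$samples_per_tissue
  tissue_names <- sprintf("sim_tissue_%02d", seq_len(nT))
  mult <- rep(1, nT)
  mult[cfg$heterogeneous_tissue] <- cfg$heterogeneous_sd_multiplier
  mult[cfg$quiet_tissue] <- cfg$quiet_sd_multiplier

  # cohort structure (donors, sexes, sample assignment) from the root seed
  set.seed(cfg$seed)
  subj_ids <- sprintf("SYN-%04d", seq_len(cfg$n_subjects))
  subj_sex <- ifelse(runif(cfg$n_subjects) < cfg$male_fraction, "male", "female")
  subj_age <- sample(c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79"),
                     cfg$n_subjects, replace = TRUE)
  tissue_subj <- lapply(seq_len(nT), function(t) {
    sample.int(cfg$n_subjects, sizes[t])
  })
  sample_ids <- lapply(seq_len(nT), function(t) {
    paste0(subj_ids[tissue_subj[[t]]], "-", sprintf("%02d", t), "-SM")
  })
  sample_sex <- lapply(seq_len(nT), function(t) subj_sex[tissue_subj[[t]]])

  # gene registry with planted class labels
  counts <- c(
    stable_housekeeping = cfg$n_stable,
    tissue_specific = cfg$n_tissue_specific,
    within_tissue_stable_tissue_variable = cfg$n_tissue_variable,
    heterogeneous_marker = cfg$n_heterogeneous,
    sex_dimorphic = cfg$n_sex_dimorphic,
    silent = cfg$n_silent,
    background_noncoding = cfg$n_noncoding
  )
  classes <- rep(names(counts), counts)
  nG <- length(classes)
  gene_ids <- sprintf("SYNG%05d.1", seq_len(nG))
  designated <- rep(NA_integer_, nG)
  is_ts <- classes == "tissue_specific"
  designated[is_ts] <- rep_len(seq_len(nT), sum(is_ts))
  designated[classes == "heterogeneous_marker"] <- cfg$heterogeneous_tissue
  designated[classes == "sex_dimorphic"] <- cfg$sex_tissue

  mats <- lapply(sizes, function(n) matrix(0, nG, n))
  draw_lnorm_by_tissue <- function(mu, sd_by_tissue) {
    lapply(seq_len(nT), function(t) rlnorm(sizes[t], mu[t], sd_by_tissue[t]))
  }
  for (g in seq_len(nG)) {
    set.seed(substream_seed(cfg$seed, gene_ids[g]))
    cls <- classes[g]
    vals <- switch(cls,
      stable_housekeeping = {
        b <- rnorm(1, cfg$stable_log_mean, cfg$baseline_log_sd)
        mu <- b + rnorm(nT, 0, cfg$between_sd_stable)
        draw_lnorm_by_tissue(mu, cfg$within_sd * mult)
      },
      within_tissue_stable_tissue_variable = {
        b <- rnorm(1, cfg$variable_log_mean, cfg$baseline_log_sd)
        mu <- b + rnorm(nT, 0, cfg$between_sd_variable)
        draw_lnorm_by_tissue(mu, cfg$within_sd * mult)
      },
      tissue_specific = {
        d <- designated[g]
        mu_d <- rnorm(1, cfg$specific_log_mean, 0.3)
        lapply(seq_len(nT), function(t) {
          if (t == d) {
            # home-tissue dispersion is the class's own parameter; the
            # per-tissue heterogeneity multiplier models broadly expressed
            # genes and does not apply here
            rlnorm(sizes[t], mu_d, cfg$specific_within_sd)
          } else {
            v <- rlnorm(sizes[t], cfg$leak_log_mean, cfg$leak_sd)
            v[runif(sizes[t]) < cfg$specific_dropout] <- 0
            v
          }
        })
      },
      heterogeneous_marker = {
        b <- rnorm(1, cfg$hetero_log_mean, cfg$baseline_log_sd)
        mu <- b + rnorm(nT, 0, cfg$hetero_between_sd)
        sds <- cfg$hetero_base_sd * mult
        sds[cfg$heterogeneous_tissue] <- cfg$hetero_sd
        draw_lnorm_by_tissue(mu, sds)
      },
      sex_dimorphic = {
        b <- rnorm(1, cfg$sex_log_mean, cfg$baseline_log_sd)
        mu <- b + rnorm(nT, 0, 0.05)
        lapply(seq_len(nT), function(t) {
          if (t == cfg$sex_tissue) {
            sdv <- ifelse(sample_sex[[t]] == "male",
                          cfg$sex_sd_high, cfg$sex_sd_low)
            rlnorm(sizes[t], mu[t], sdv)
          } else {
            rlnorm(sizes[t], mu[t], cfg$sex_base_sd * mult[t])
          }
        })
      },
      silent = lapply(sizes, function(n) numeric(n)),
      background_noncoding = {
        b <- rnorm(1, cfg$noncoding_log_mean, cfg$baseline_log_sd)
        lapply(seq_len(nT), function(t) {
          v <- rlnorm(sizes[t], b, cfg$noncoding_sd)
          v[runif(sizes[t]) < cfg$noncoding_dropout] <- 0
          v
        })
      }
    )
    for (t in seq_len(nT)) {
      mats[[t]][g, ] <- vals[[t]]
    }
  }

  ems <- lapply(seq_len(nT), function(t) {
    m <- mats[[t]]
    dimnames(m) <- list(gene_ids, sample_ids[[t]])
    expression_matrix(tissue_names[t], m,
                      symbols = sprintf("GS%05d", seq_len(nG)))
  })
  subjects <- data.frame(
    subject_id = subj_ids, sex = subj_sex, age = subj_age,
    stringsAsFactors = FALSE
  )
  cohort <- assemble_cohort(ems, subjects, exclude_tissues = character())
  catalog <- gene_catalog(
    gene_id = gene_ids,
    symbol = sprintf("GS%05d", seq_len(nG)),
    biotype = ifelse(classes == "background_noncoding", "lncRNA",
                     "protein_coding"),
    chromosome = paste0("chr", (seq_len(nG) - 1L) %% 22L + 1L)
  )
  truth <- data.frame(
    gene_id = gene_ids,
    class = classes,
    designated_tissue = ifelse(is.na(designated), NA_character_,
                               tissue_names[designated]),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, catalog = catalog, truth = truth, config = cfg)
}

#' Evaluate recovery of the planted stable class
#'
#' Scores a [call_housekeeping()] result against the generator's truth
#' labels: precision and recall of each called list with respect to the
#' `stable_housekeeping` class, plus per-class confusion counts for each
#' list. Precision of an empty list is undefined (`NA`).
#'
#' @param call a `housekeeping_call`.
#' @param truth the `truth` data frame from [generate_cohort()].
#' @return list with `metrics` (data frame: list, n_called, n_true,
#'   true_positives, precision, recall) and `confusion` (data frame:
#'   list, class, n_called).
#' @export
evaluate_recovery <- function(call, truth) {
  stopifnot(inherits(call, "housekeeping_call"))
  lists <- list(
    subject_axis = call$subject_axis,
    tissue_axis = call$tissue_axis,
    intersection = call$intersection
  )
  unknown <- setdiff(unlist(lists, use.names = FALSE), truth$gene_id)
  if (length(unknown)) {
    stop("called gene '", unknown[1L], "' is absent from the truth labels",
         call. = FALSE)
  }
  stable <- truth$gene_id[truth$class == "stable_housekeeping"]
  metrics <- do.call(rbind, lapply(names(lists), function(nm) {
    l <- lists[[nm]]
    tp <- length(intersect(l, stable))
    data.frame(
      list = nm,
      n_called = length(l),
      n_true = length(stable),
      true_positives = tp,
      precision = if (length(l)) tp / length(l) else NA_real_,
      recall = if (length(stable)) tp / length(stable) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  confusion <- do.call(rbind, lapply(names(lists), function(nm) {
    cls <- truth$class[truth$gene_id %in% lists[[nm]]]
    data.frame(
      list = nm,
      class = SIM_CLASSES,
      n_called = vapply(SIM_CLASSES, function(k) sum(cls == k), 0L),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }))
  list(metrics = metrics, confusion = confusion)
}
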