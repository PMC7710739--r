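#' immunodyn: longitudinal tumor immune dynamics from serial biopsies
#'
#' Tools to analyze serial tumor biopsy cohorts across treatment time
#' points: mixed-model differential expression, single-sample gene-set
#' scoring, immune cell deconvolution, immune-state classification and
#' transitions, NMF virtual microdissection, H&E-style TIL quantification,
#' and outcome association — plus a synthetic cohort generator with ground
#' truth so the whole pipeline is testable without patient data.
#'
#' @keywords internal
"_PACKAGE"

#' Default pipeline configuration
#'
#' A self-contained synthetic demo configuration. One global seed fans out
#' to per-stage seeds by fixed offsets.
#'
#' @param output_dir where stage outputs go.
#' @param seed global integer seed.
#' @return named list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(output_dir = tempfile("immunodyn_run_"),
                                    seed = 42L) {
  list(seed = as.integer(seed), output_dir = output_dir,
       stages = list(simulate = TRUE, score = TRUE, de = TRUE,
                     cluster = TRUE, deconvolve = TRUE, states = TRUE,
                     microdissect = TRUE, til = TRUE, outcome = TRUE),
       synthetic = list(n_patients = 40, n_genes = 400,
                        signature_blocks = c(immune = 40, cell_cycle = 40,
                                             emt = 40)),
       de = list(p_cut = 0.01, lfc_cut = 1),
       consensus = list(k = 3, n_resamples = 30, subsample_frac = 0.8),
       deconv = list(n_mixtures = 30, noise_sd = 5),
       states = list(k = 3, penalty = 0.2),
       nmf = list(k = 3, n_runs = 5, max_iter = 500),
       til = list(width = 1200, height = 1200, n_lymphocytes = 60,
                  n_other = 25),
       outcome = list(n_boot = 200, alpha = 0.5))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return config list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  modifyList(cfg, user)
}

pipe_write <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in order (simulate, score, DE, cluster, deconvolve,
#' states, microdissect, TIL, outcome), writing per-stage CSV/TSV/JSON
#' outputs plus a JSON summary carrying consort and transition percentages,
#' the config hash and all derived seeds. Fully reproducible from the
#' global seed. Toggled-off stages make dependent stages fail fast.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()], or a YAML path.
#' @return invisibly, the summary list (also written to
#'   `summary.json` in the output directory).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage_seed <- function(offset) seed + offset
  on_stage <- function(s) isTRUE(config$stages[[s]])
  need <- function(s) if (!on_stage(s))
    stop("stage '", s, "' is required by a later stage but toggled off")
  summary <- list(seed = seed,
                  config_hash = sum(utf8ToInt(paste(
                    deparse(config), collapse = ""))))

  ## simulate
  need("simulate")
  sim_args <- config$synthetic
  sim_args$seed <- stage_seed(1L)
  cohort <- simulate_cohort(do.call(simulation_config, sim_args))
  expr_log <- log_transform(cohort$expression)
  write_expression(cohort$expression, file.path(config$output_dir,
                                                "expression_tpm.tsv"))
  write_clinical(cohort$clinical, file.path(config$output_dir,
                                            "clinical.csv"))
  cons <- consort_summary(cohort$clinical)
  pipe_write(cons, config$output_dir, "consort.csv")
  summary$n_patients <- length(unique(cohort$clinical$patient_id))
  summary$n_samples <- nrow(cohort$clinical)
  summary$pcr_percent <-
    cons$percent[cons$section == "pcr" & cons$level == "pCR"]

  ## gene-set scores on the planted blocks
  blocks <- names(cohort$truth$config$signature_blocks)
  sets <- lapply(blocks, function(b)
    cohort$truth$gene_effects$gene_id[cohort$truth$gene_effects$block == b])
  names(sets) <- blocks
  scores <- NULL
  if (on_stage("score")) {
    scores <- gsva_scores(expr_log, sets)
    utils::write.table(scores, file.path(config$output_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE)
  }

  ## differential expression + clustering
  de <- NULL
  if (on_stage("de")) {
    de <- run_de(expr_log, cohort$clinical)
    pipe_write(de, config$output_dir, "de_results.csv")
    de_genes <- select_de_genes(de, config$de$p_cut, config$de$lfc_cut)
    summary$n_de_genes <- length(de_genes)
    if (on_stage("cluster") && length(de_genes) >= config$consensus$k) {
      cc <- consensus_kmeans(expr_log[de_genes, , drop = FALSE],
                             cohort$clinical, k = config$consensus$k,
                             n_resamples = config$consensus$n_resamples,
                             subsample_frac = config$consensus$subsample_frac,
                             seed = stage_seed(2L))
      pipe_write(data.frame(gene = names(cc$labels), cluster = cc$labels),
                 config$output_dir, "gene_clusters.csv")
    }
  }

  ## deconvolution on synthetic mixtures from the default signature
  frac <- NULL
  if (on_stage("deconvolve")) {
    sig <- synthetic_signature_matrix()
    mix <- simulate_mixtures(sig, config$deconv$n_mixtures,
                             noise_sd = config$deconv$noise_sd,
                             seed = stage_seed(3L))
    frac <- nusvr_deconvolve(mix$mixture, sig)
    utils::write.table(frac$fractions,
                       file.path(config$output_dir, "cell_fractions.tsv"),
                       sep = "\t", quote = FALSE)
    summary$deconv_mae <- mean(abs(frac$fractions - mix$fractions))
  }

  ## immune states on score + CYT blocks
  if (on_stage("states")) {
    if (is.null(scores)) need("score")
    imm <- t(scores)
    cyt <- log2(colMeans(2^expr_log[sets$immune[1:5], , drop = FALSE]))
    istate <- integrative_cluster(list(imm), k = config$states$k,
                                  penalty = config$states$penalty,
                                  seed = stage_seed(4L))
    score_sum <- as.numeric(scale(imm[, "immune"]))
    names(score_sum) <- rownames(imm)
    lab <- label_states(istate, score_sum)
    pipe_write(data.frame(sample_id = names(lab), state = unname(lab)),
               config$output_dir, "immune_states.csv")
    pr <- build_pairs(cohort$clinical, "T1", "T2")
    tt <- transition_table(lab, pr)
    tp <- transition_percentages(tt)
    pipe_write(tp, config$output_dir, "transitions_t1_t2.csv")
    summary$transitions_t1_t2 <- tp
  }

  ## virtual microdissection
  if (on_stage("microdissect")) {
    nm <- nmf_brunet(expr_log, k = config$nmf$k, n_runs = config$nmf$n_runs,
                     max_iter = config$nmf$max_iter, seed = stage_seed(5L))
    utils::write.table(nm$W, file.path(config$output_dir, "nmf_W.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(nm$H, file.path(config$output_dir, "nmf_H.tsv"),
                       sep = "\t", quote = FALSE)
    ex <- exemplar_genes(nm$W)
    summary$nmf_error <- nm$error
    summary$n_exemplars <- sum(lengths(ex))
  }

  ## TIL imaging
  if (on_stage("til")) {
    sim_img <- simulate_histology_image(config$til$width, config$til$height,
                                        config$til$n_lymphocytes,
                                        config$til$n_other,
                                        seed = stage_seed(6L))
    clf <- train_til_classifier(seed = stage_seed(7L))
    q <- quantify_tils(sim_img$image, clf)
    summary$til_density <- q$density
    summary$til_count <- q$lymphocyte_count
    summary$til_planted <- config$til$n_lymphocytes
  }

  ## outcome association
  if (on_stage("outcome")) {
    if (is.null(scores)) need("score")
    clin <- cohort$clinical
    pat <- unique(clin$patient_id)
    feat <- t(sapply(pat, function(p) {
      s1 <- clin$sample_id[clin$patient_id == p & clin$time == "T1"]
      s2 <- clin$sample_id[clin$patient_id == p & clin$time == "T2"]
      c(immune_T1 = unname(scores["immune", s1]),
        immune_T2 = unname(scores["immune", s2]))
    }))
    out_pcr <- clin$pcr[match(pat, clin$patient_id)]
    usage <- elasticnet_bootstrap(feat, out_pcr,
                                  n_boot = max(100, config$outcome$n_boot),
                                  alpha = config$outcome$alpha,
                                  seed = stage_seed(8L))
    pipe_write(usage$table, config$output_dir, "variable_usage.csv")
    summary$top_feature <- usage$table$feature[[1]]
  }

  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Run the built-in synthetic demo
#' @param seed global seed, default 42.
#' @param output_dir output directory.
#' @return the pipeline summary, invisibly.
#' @export
pipeline_demo <- function(seed = 42L, output_dir = tempfile("immunodyn_demo_")) {
  run_pipeline(default_pipeline_config(output_dir = output_dir, seed = seed))
}
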