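# End-to-end orchestration: per-subject pipeline runs and multi-subject,
# multi-cohort studies with cross-rate consistency summaries.

#' Run the TDA temporal clustering pipeline on one subject-cohort
#'
#' Correlation-to-distance transform, per-timepoint H0 persistence diagram,
#' pairwise Wasserstein distance matrix, 2-D metric MDS, then
#' silhouette-selected k-means.
#'
#' @param fcn A `tempoph_fcn` for one subject-cohort.
#' @param k_min,k_max,seed As in [select_k()].
#' @param distance_formula Passed to [correlation_to_distance()].
#' @param wd_order,wd_internal Passed to [pairwise_wd_matrix()].
#' @param keep_intermediates If `TRUE`, attach diagrams, the Wasserstein
#'   matrix and the embedding as attribute `intermediates`.
#' @return A `tempoph_clusters` with pipeline tag `"tda"`.
#' @export
run_tda_subject <- function(fcn, k_min = 2, k_max = 16, seed = 1L,
                            distance_formula = "sqrt_half",
                            wd_order = 1, wd_internal = "Linf",
                            keep_intermediates = FALSE) {
  stopifnot(inherits(fcn, "tempoph_fcn"))
  dists <- correlation_to_distance(fcn, formula = distance_formula)
  Tn <- dim(dists$matrices)[1]
  diagrams <- lapply(seq_len(Tn), function(t) {
    compute_h0_diagram(dists$matrices[t, , ])
  })
  wd <- pairwise_wd_matrix(diagrams, q = wd_order, internal = wd_internal)
  emb <- mds_embed(wd, n_components = 2, seed = seed)
  res <- select_k(emb$coords, k_min = k_min, k_max = k_max, seed = seed,
                  pipeline = "tda")
  if (keep_intermediates)
    attr(res, "intermediates") <- list(diagrams = diagrams, wd = wd,
                                       embedding = emb)
  res
}

run_one_pipeline <- function(pipeline, fcn, k_min, k_max, seed, ...) {
  switch(pipeline,
         tda = run_tda_subject(fcn, k_min, k_max, seed, ...),
         direct = direct_cluster(fcn, k_min, k_max, seed),
         pca = pca_cluster(fcn, k_min, k_max, seed),
         dfcn = traditional_cluster(fcn, k_min, k_max, seed),
         stop_param("unknown pipeline '%s'", pipeline))
}

#' Run a multi-subject, multi-cohort synthetic study
#'
#' Generates `n_subjects` synthetic subjects from `config` (each subject
#' gets its own latent trajectory via a seed substream; each subject's
#' cohorts share ONE trajectory), runs the selected pipelines on every
#' (subject, cohort) cell, and summarizes cross-cohort consistency of the
#' chosen cluster counts per pipeline: cohort-wide distances (with the
#' default report threshold <= 1), pairwise distances (threshold <= 2), and
#' the cluster-count distribution per cohort.
#'
#' Per-cell failures are recorded and do not abort the study.
#'
#' @param config A [synthetic_config()] with at least 2 cohorts.
#' @param pipelines Subset of `c("tda", "direct", "pca", "dfcn")`.
#' @param n_subjects Number of subjects to simulate.
#' @param seed Study seed; all per-subject and per-cell seeds derive from
#'   it through [seed_substream()].
#' @param k_min,k_max Candidate cluster range.
#' @return A `tempoph_study`: list with `schema_version`, `config` echo,
#'   `subjects` (per subject: per pipeline: per cohort `chosen_k`,
#'   `silhouette_by_k`, `labels` or `error`) and `consistency` (per
#'   pipeline summary).
#' @export
run_study <- function(config, pipelines = "tda", n_subjects = 10,
                      seed = config$seed, k_min = 2, k_max = 16) {
  stopifnot(inherits(config, "tempoph_config"))
  if (length(config$tr_list) < 2L)
    stop_param("consistency analysis needs at least 2 cohorts")
  pipelines <- match.arg(pipelines, c("tda", "direct", "pca", "dfcn"),
                         several.ok = TRUE)
  n_subjects <- check_count(n_subjects, "n_subjects", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  tags <- cohort_tag(config$tr_list)

  subjects <- lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("sub-%03d", i)
    cfg_i <- config
    cfg_i$seed <- seed_substream(seed, paste0("subject:", sid))
    sim <- simulate_fcn_sequence(cfg_i)
    pl <- lapply(pipelines, function(p) {
      cohorts <- lapply(tags, function(tag) {
        cell_seed <- seed_substream(seed, paste(sid, tag, p, sep = ":"))
        res <- tryCatch(
          run_one_pipeline(p, sim$cohorts[[tag]], k_min, k_max, cell_seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          list(cohort = tag, error = conditionMessage(res))
        } else {
          list(cohort = tag,
               chosen_k = res$chosen_k,
               silhouette_by_k = as.list(res$silhouette_by_k),
               labels = res$labels)
        }
      })
      names(cohorts) <- tags
      list(pipeline = p, cohorts = cohorts)
    })
    names(pl) <- pipelines
    list(subject_id = sid, planted_k = sim$ground_truth$planted_k,
         pipelines = pl)
  })

  consistency <- lapply(pipelines, function(p) {
    counts <- lapply(subjects, function(s) {
      ks <- vapply(tags, function(tag) {
        cell <- s$pipelines[[p]]$cohorts[[tag]]
        if (is.null(cell$chosen_k)) NA_integer_ else as.integer(cell$chosen_k)
      }, integer(1))
      ks
    })
    complete <- !vapply(counts, anyNA, logical(1))
    cw <- if (length(tags) == 3L) {
      vapply(counts[complete], cohort_distance, integer(1))
    } else {
      # generalized: sum over all unordered cohort pairs
      vapply(counts[complete], function(k) sum(pairwise_distances(k)),
             numeric(1))
    }
    pw <- lapply(counts[complete], pairwise_distances)
    pair_names <- if (length(pw) > 0L) names(pw[[1]]) else character(0)
    pw_summary <- lapply(pair_names, function(pn) {
      d <- vapply(pw, `[[`, numeric(1), pn)
      list(pair = pn, distances = as.integer(d),
           pct_within_2 = proportion_within(d, 2))
    })
    names(pw_summary) <- pair_names
    dist_by_cohort <- lapply(tags, function(tag) {
      ks <- vapply(subjects, function(s) {
        cell <- s$pipelines[[p]]$cohorts[[tag]]
        if (is.null(cell$chosen_k)) NA_integer_ else as.integer(cell$chosen_k)
      }, integer(1))
      ks <- ks[!is.na(ks)]
      if (length(ks) == 0L) return(NULL)
      cluster_count_distribution(ks, group = tag)
    })
    names(dist_by_cohort) <- tags
    list(pipeline = p,
         n_subjects = n_subjects,
         n_complete = sum(complete),
         cohortwide_distances = as.integer(cw),
         pct_within_1 = if (length(cw) > 0L) proportion_within(cw, 1)
                        else NA_real_,
         pairwise = pw_summary,
         count_distribution = dist_by_cohort)
  })
  names(consistency) <- pipelines

  structure(list(schema_version = "1.0",
                 study = list(n_subjects = n_subjects,
                              seed = seed,
                              pipelines = pipelines,
                              cohorts = tags,
                              k_range = c(k_min, k_max),
                              planted_k = config$n_states),
                 subjects = subjects,
                 consistency = consistency),
            class = "tempoph_study")
}
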