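# End-to-end orchestration on a synthetic cohort: simulate -> prepare ->
# gradients -> metrics -> age effects -> spatial nulls -> coupling -> PLSC
# -> PLSR/enrichment, with every stage output written to a run directory
# and recorded in a manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()].  Embedding,
#' spline, and resampling defaults mirror the analysis conventions of the
#' method (alpha = 0.5, spline k = 3, six age bins, top-10% FC threshold);
#' resampling counts are kept moderate here and should be raised to 1,000
#' for production inference.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_nodes = 100L, n_communities = 4L,
    n_subjects = 100L, age_range = c(6, 14),
    age_slope = 0.05,
    embedding = list(n_components = 10L, alpha = 0.5),
    bins = age_bin_breaks_default,
    age_model = list(k = 3L, random_intercept = TRUE),
    nulls = list(n_surrogates = 100L, resample = FALSE),
    fc = list(threshold = 0.10),
    plsc = list(n_perm = 200L, n_boot = 200L),
    genes = list(enabled = TRUE, n_genes = 200L, n_signal = 20L,
                 loading = 0.8, n_boot = 200L),
    gene_sets = NULL,                   # optional path to a GMT file
    write_scan_matrices = FALSE
  )
}

write_tsv <- function(x, path) {
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes all stages in dependency order and writes their outputs (TSV
#' and JSON) plus a `manifest.json` with the configuration snapshot, seed,
#' file hashes, and stage wall times to `out_dir`.  Rerunning with the same
#' configuration reproduces the numeric outputs exactly.  When
#' `config$genes$enabled` is `FALSE` the transcriptomic stages are skipped
#' cleanly.
#'
#' @param config Configuration list; see [default_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  times <- list()
  files <- character(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    times[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- simulate ------------------------------------------------------------
  sim <- tick("simulate", {
    parcels <- make_parcels(config$n_nodes, config$n_communities)
    truth <- planted_truth(parcels, age_slope = config$age_slope,
                           seed = config$seed)
    cohort <- simulate_cohort(parcels, truth, n_subjects = config$n_subjects,
                              age_range = config$age_range,
                              seed = config$seed)
    list(parcels = parcels, truth = truth, cohort = cohort)
  })
  files <- c(files,
             write_tsv(as.data.frame(sim$parcels),
                       file.path(out_dir, "parcels.tsv")),
             write_tsv(sim$cohort$phenotypes,
                       file.path(out_dir, "phenotypes.tsv")))
  if (isTRUE(config$write_scan_matrices)) {
    for (sc in sim$cohort$scans) {
      d <- file.path(out_dir, "scans", sc$scan_id)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      files <- c(files,
                 write_tsv(as.data.frame(sc$gd), file.path(d, "gd.tsv")),
                 write_tsv(as.data.frame(sc$profiles),
                           file.path(d, "profiles.tsv")),
                 write_tsv(as.data.frame(sc$ts), file.path(d, "ts.tsv")),
                 write_tsv(as.data.frame(sc$fc), file.path(d, "fc.tsv")))
    }
  }

  # -- gradients -----------------------------------------------------------
  grads <- tick("gradients", {
    cohort_gradients(sim$cohort, breaks = config$bins,
                     k = config$embedding$n_components,
                     alpha = config$embedding$alpha,
                     orient_to = sim$truth$contrast_vector)
  })
  g1 <- t(vapply(grads$gradients, function(g) g$components[, 1],
                 numeric(config$n_nodes)))
  files <- c(files,
             write_tsv(data.frame(scan_id = rownames(g1), g1,
                                  check.names = FALSE),
                       file.path(out_dir, "gradient1.tsv")))

  # -- metrics -------------------------------------------------------------
  metrics <- tick("metrics", {
    tmpl_centroid <- gradient_space(grads$templates$overall)$centroid
    rows <- lapply(names(grads$gradients), function(id) {
      g <- grads$gradients[[id]]
      sp <- gradient_space(g)
      m1 <- global_measures(g, 1L)
      m3 <- global_measures(g, 3L)
      data.frame(scan_id = id,
                 range_g1 = m1$range, sd_g1 = m1$sd,
                 expl_g1 = m1$explanation_ratio,
                 range_g3 = m3$range, sd_g3 = m3$sd,
                 dispersion = dispersion(sp),
                 mean_eccentricity = mean(eccentricity(sp, tmpl_centroid)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  files <- c(files, write_tsv(metrics, file.path(out_dir, "metrics.tsv")))

  # -- age effects ---------------------------------------------------------
  phen <- sim$cohort$phenotypes
  ages <- tick("age_effects", {
    k <- config$age_model$k
    ri <- config$age_model$random_intercept
    global <- lapply(c(dispersion = "dispersion", range_g1 = "range_g1",
                       sd_g1 = "sd_g1"), function(v) {
      r <- delta_adj_r2(metrics[[v]], phen, k = k, random_intercept = ri)
      data.frame(measure = v, delta_adj_r2 = r$delta_adj_r2, p = r$p)
    })
    nodewise <- nodewise_age_effects(g1, phen, k = k, random_intercept = ri)
    list(global = do.call(rbind, c(global, list(make.row.names = FALSE))),
         nodewise = nodewise)
  })
  files <- c(files,
             write_tsv(ages$global, file.path(out_dir, "age_global.tsv")),
             write_tsv(ages$nodewise$effects,
                       file.path(out_dir, "age_effects.tsv")),
             write_tsv(as.data.frame(ages$nodewise$trajectories),
                       file.path(out_dir, "trajectories.tsv")))

  # -- coupling and spatial nulls ------------------------------------------
  coupling <- tick("coupling", {
    dmat <- parcel_distance(sim$parcels)
    fc_mean <- Reduce(`+`, lapply(sim$cohort$scans, `[[`, "fc")) /
      length(sim$cohort$scans)
    fcg <- fc_gradient(fc_mean, k = config$embedding$n_components,
                       threshold = config$fc$threshold,
                       alpha = config$embedding$alpha)
    fcg <- orient_gradients(fcg, sim$truth$contrast_vector)
    aff_mean <- Reduce(`+`, lapply(grads$prepped, function(p) {
      build_multiscale_affinity(p$gd, p$mpc, p$ts)$values
    })) / length(grads$prepped)
    rho <- nodal_coupling(aff_mean, fc_mean)
    fc_pos <- pmax(fc_mean, 0); diag(fc_pos) <- 0
    aff0 <- aff_mean; diag(aff0) <- 0
    pac_s <- participation_coefficient(aff0, sim$parcels$community)
    pac_f <- participation_coefficient(fc_pos, sim$parcels$community)
    eff_map <- ages$nodewise$effects$delta_adj_r2
    ens <- make_surrogates(eff_map, dmat, n = config$nulls$n_surrogates,
                           params = config$nulls, seed = config$seed)
    test_fc <- surrogate_corr_test(eff_map, fcg$components[, 1], ens)
    list(rho = rho, pac_structural = pac_s, pac_functional = pac_f,
         fc_gradient = fcg, effect_vs_fc_gradient = test_fc,
         distance = dmat, effect_map = eff_map)
  })
  files <- c(files,
             write_tsv(data.frame(node = sim$parcels$node_id,
                                  coupling = coupling$rho,
                                  pac_structural = coupling$pac_structural,
                                  pac_functional = coupling$pac_functional,
                                  fc_g1 = coupling$fc_gradient$components[, 1]),
                       file.path(out_dir, "coupling.tsv")))

  # -- PLSC ----------------------------------------------------------------
  plsc_res <- tick("plsc", {
    beh_cols <- grep("^beh", names(phen), value = TRUE)
    plsc(g1, as.matrix(phen[beh_cols]),
         n_perm = config$plsc$n_perm, n_boot = config$plsc$n_boot,
         seed = config$seed)
  })
  plsc_json <- file.path(out_dir, "plsc.json")
  jsonlite::write_json(list(
    singular_values = plsc_res$s,
    perm_p = plsc_res$perm_p,
    lc1_score_correlation = stats::cor(plsc_res$lx[, 1], plsc_res$ly[, 1])
  ), plsc_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, plsc_json)

  # -- PLSR / enrichment (optional) ----------------------------------------
  plsr_res <- NULL
  if (isTRUE(config$genes$enabled)) {
    plsr_res <- tick("plsr", {
      genes <- simulate_gene_matrix(sim$parcels, sim$truth,
                                    n_genes = config$genes$n_genes,
                                    n_signal_genes = config$genes$n_signal,
                                    loading = config$genes$loading,
                                    seed = config$seed)
      pr <- plsr_genes(coupling$effect_map, genes,
                       n_boot = config$genes$n_boot, seed = config$seed)
      enr <- NULL
      if (!is.null(config$gene_sets)) {
        sets <- read_gmt(config$gene_sets)
        enr <- hypergeom_enrichment(pr$top_positive, sets, colnames(genes))
      }
      list(plsr = pr, enrichment = enr, genes = genes)
    })
    ranked <- data.frame(gene = names(plsr_res$plsr$bootstrap_z),
                         weight = plsr_res$plsr$gene_weights,
                         z = plsr_res$plsr$bootstrap_z)
    ranked <- ranked[order(-ranked$z), ]
    files <- c(files,
               write_tsv(ranked, file.path(out_dir, "genes_ranked.tsv")))
    if (!is.null(plsr_res$enrichment)) {
      files <- c(files, write_tsv(plsr_res$enrichment,
                                  file.path(out_dir, "enrichment.tsv")))
    }
  }

  manifest <- list(
    config = config,
    seed = config$seed,
    files = lapply(stats::setNames(nm = basename(files)), function(f) {
      unname(tools::md5sum(files[basename(files) == f][1]))
    }),
    stage_seconds = times
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, gradients = grads, metrics = metrics,
                 age_effects = ages, coupling = coupling, plsc = plsc_res,
                 plsr = plsr_res, manifest = manifest))
}
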