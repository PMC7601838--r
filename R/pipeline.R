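#' Extract the per-patient feature row
#'
#' Computes, for one (synthetic or loaded) patient: lesion and glandular ADC
#' ROI statistics and the normalized ADC ratio; the 51 single-parameter
#' radiomic features of the post-contrast DCE channel over the lesion ROI;
#' radiomic-feature-map means; and the multiparametric tissue-signature
#' features over all channels. Clinical descriptors are carried through.
#'
#' @param patient a `synthetic_patient` (or any list with `volumes`,
#'   `lesion_mask`, `glandular_mask`, `clinical`, `id`).
#' @param G gray levels (default 64).
#' @param distance GLCM offset (default 1).
#' @param B signature bins per channel (default 8).
#' @param rfm_features RFM map names (default the headline entropy /
#'   uniformity / filter maps); `NULL` skips RFM.
#' @param window RFM window (default 5).
#' @param texture_channel channel used for single radiomics (default "dce").
#' @return One-row data.frame of named features.
#' @export
patient_features <- function(patient, G = 64L, distance = 1L, B = 8L,
                             rfm_features = c("fos_entropy", "fos_uniformity",
                                              "glcm_entropy", "glcm_energy",
                                              "laplacian", "log"),
                             window = 5L, texture_channel = "dce") {
  vols <- patient$volumes
  lm <- patient$lesion_mask
  gm <- patient$glandular_mask
  adc_l <- roi_stats(vols$channels$adc, lm)
  adc_g <- roi_stats(vols$channels$adc, gm)
  ch <- vols$channels[[texture_channel]]
  single <- radiomic_vector(ch, lm, G = G, distance = distance)
  mp <- mprad_features(vols, lm, B = B, distance = distance)
  rfm <- if (!is.null(rfm_features))
    rfm_maps(ch, lm, features = rfm_features, window = window, G = G,
             distance = distance)$means else NULL
  row <- c(list(id = patient$id), patient$clinical,
           list(adc_lesion = adc_l$mean, adc_lesion_sd = adc_l$sd,
                adc_glandular = adc_g$mean,
                adc_ratio = normalized_adc(adc_l$mean, adc_g$mean)),
           as.list(single), as.list(mp), as.list(rfm))
  as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with validated defaults: gray levels 64,
#' GLCM distance 1, RFM window 5, signature bins 8, correlation threshold
#' 0.5, network neighborhood k = 3, classifier grid around
#' (k_iso 60, d_iso 10, ratio 2).
#'
#' @param spec a [cohort_spec()] for the simulate stage.
#' @param stages character subset of
#'   `c("simulate","features","embed","network","classify")`.
#' @param G,distance,window,B,threshold,k_nldr,k_network,k_iso,d_iso,ratio
#'   stage parameters.
#' @param rfm_features RFM maps computed in the feature stage.
#' @param embed_params,classify_params feature-column subsets used by the
#'   embedding and classification stages (defaults cover the clinical,
#'   quantitative-imaging and headline radiomic parameters).
#' @param tune tune each inter-group comparison by LOOCV over `grid`
#'   (default TRUE); with FALSE the fixed (k_iso, d_iso, ratio) is used.
#' @param grid tuning grid (data.frame with k_iso, d_iso, ratio).
#' @param n_boot ROC bootstrap resamples.
#' @param seed pipeline seed (also seeds the cohort spec unless it sets its
#'   own).
#' @param out_dir output directory (`NULL` for none).
#' @return Validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(spec = cohort_spec(),
                            stages = c("simulate", "features", "embed",
                                       "network", "classify"),
                            G = 64L, distance = 1L, window = 5L, B = 8L,
                            threshold = 0.5, k_nldr = 10L, k_network = 3L,
                            k_iso = 60L, d_iso = 10L, ratio = 2,
                            rfm_features = c("fos_entropy", "fos_uniformity",
                                             "glcm_entropy", "glcm_energy",
                                             "laplacian", "log"),
                            embed_params = NULL, classify_params = NULL,
                            tune = TRUE,
                            grid = expand.grid(k_iso = c(20L, 40L, 60L),
                                               d_iso = c(5L, 10L),
                                               ratio = c(1, 2)),
                            n_boot = 2000L, seed = 7L, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(G >= 2, distance >= 1, window >= 3, window %% 2 == 1, B >= 2,
            threshold >= 0, threshold <= 1, k_nldr >= 1, k_network >= 1,
            d_iso >= 1, k_iso >= d_iso + 1, ratio >= 1, n_boot >= 1)
  if (is.null(embed_params))
    embed_params <- c("ki67", "lesion_size_cm", "ktrans", "kep", "ve",
                      "dce_peak", "morphology", "kinetic_type", "adc_lesion",
                      "adc_ratio", "FOS_entropy", "FOS_uniformity",
                      "GLCM_entropy", "GLCM_energy")
  if (is.null(classify_params))
    classify_params <- c("adc_lesion", "adc_ratio", "ktrans", "kep", "ve",
                         "ki67", "FOS_entropy", "FOS_uniformity",
                         "GLCM_entropy", "GLCM_energy")
  structure(list(spec = spec, stages = stages, G = as.integer(G),
                 distance = as.integer(distance), window = as.integer(window),
                 B = as.integer(B), threshold = threshold,
                 k_nldr = as.integer(k_nldr), k_network = as.integer(k_network),
                 k_iso = as.integer(k_iso), d_iso = as.integer(d_iso),
                 ratio = ratio, rfm_features = rfm_features,
                 embed_params = embed_params, classify_params = classify_params,
                 tune = isTRUE(tune), grid = grid,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (phantom cohort) -> features (ADC statistics,
#' single radiomics, RFM, multiparametric radiomics) -> embed (multi-subspace
#' model and heatmap) -> network (parameter interaction graph, centralities,
#' hubs) -> classify (four inter-group Isomap+SVM comparisons with LOOCV
#' decision values and ROC). Every intermediate table is written when
#' `out_dir` is set, and a manifest records the configuration, seed and the
#' files written; a rerun with the same config and seed is bit-identical.
#' With an empty retained-embedding set the pipeline warns and continues:
#' classification runs on the raw feature columns.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated cohort (skips the simulate
#'   stage's generation).
#' @return list with `cohort`, `features` (data.frame), `iris` (the fitted
#'   multi-subspace model), `network` results, `classify` results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(manifest = list(config = config_echo(config), files = list()))
  od <- config$out_dir
  emit <- function(name, writer) {
    if (!is.null(od)) {
      if (!dir.exists(od)) dir.create(od, recursive = TRUE)
      path <- file.path(od, name)
      writer(path)
      out$manifest$files[[name]] <<- path
    }
  }

  if ("simulate" %in% config$stages && is.null(cohort)) {
    spec <- config$spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
  }
  if (is.null(cohort)) stop("stage 'simulate' disabled and no cohort supplied")
  out$cohort <- cohort
  emit("cohort.csv", function(p) write_feature_table(cohort_table(cohort), p))

  feats <- NULL
  if ("features" %in% config$stages) {
    rows <- lapply(cohort, patient_features, G = config$G,
                   distance = config$distance, B = config$B,
                   rfm_features = config$rfm_features, window = config$window)
    feats <- do.call(rbind, rows)
    feats$risk_score <- vapply(cohort, `[[`, 0, "risk_score")
    feats$risk_group <- vapply(cohort, `[[`, "", "risk_group")
    out$features <- feats
    emit("features.csv", function(p) write_feature_table(feats, p))
  }

  if ("embed" %in% config$stages) {
    if (is.null(feats)) stop("stage 'embed' requires the features stage")
    Xcols <- intersect(config$embed_params, names(feats))
    X <- as.matrix(feats[, Xcols, drop = FALSE])
    fit <- radiris(X, feats$risk_score, threshold = config$threshold,
                   k_nldr = config$k_nldr)
    out$iris <- fit
    if (!is.null(fit$heatmap)) {
      emit("heatmap.csv", function(p)
        utils::write.csv(fit$heatmap$U01, p, row.names = FALSE))
      emit("importance.csv", function(p)
        utils::write.csv(fit$importance, p, row.names = FALSE))
    }
  }

  if ("network" %in% config$stages) {
    if (is.null(feats)) stop("stage 'network' requires the features stage")
    Xcols <- intersect(config$embed_params, names(feats))
    Z <- t(vapply(Xcols, function(cn)
      risk_normalize(feats[[cn]], feats$risk_score),
      numeric(nrow(feats))))
    rownames(Z) <- Xcols
    net <- build_network(Z, k = config$k_network)
    rep_ <- centralities(net)
    out$network <- list(network = net, paths = path_metrics(net),
                        clustering = clustering_stats(net),
                        centralities = rep_,
                        hubs = hub_nodes(rep_, min(10L, nrow(rep_))))
    emit("centrality.csv", function(p)
      utils::write.csv(rep_, p, row.names = FALSE))
    emit("edges.csv", function(p) {
      el <- igraph::as_data_frame(net$graph, what = "edges")
      utils::write.csv(el, p, row.names = FALSE)
    })
  }

  if ("classify" %in% config$stages) {
    if (is.null(feats)) stop("stage 'classify' requires the features stage")
    Xcols <- intersect(config$classify_params, names(feats))
    X <- as.matrix(feats[, Xcols, drop = FALSE])
    grp <- feats$risk_group
    models <- list(
      low_vs_int  = c("low", "intermediate"),
      low_vs_high = c("low", "high"),
      int_vs_high = c("intermediate", "high"),
      low_vs_rest = NULL)
    out$classify <- lapply(names(models), function(mn) {
      if (mn == "low_vs_rest") {
        y <- factor(ifelse(grp == "low", "low", "rest"),
                    levels = c("low", "rest"))
        keep <- rep(TRUE, length(grp))
      } else {
        keep <- grp %in% models[[mn]]
        y <- factor(grp[keep], levels = models[[mn]])
      }
      if (config$tune) {
        tn <- loocv_tune(X[keep, , drop = FALSE], y, grid = config$grid)
        dec <- tn$decision; lab <- tn$labels; best <- tn$best
      } else {
        cv <- loocv_isosvm(X[keep, , drop = FALSE], y, k_iso = config$k_iso,
                           d_iso = config$d_iso, ratio = config$ratio)
        dec <- cv$decision; lab <- cv$labels
        best <- data.frame(k_iso = config$k_iso, d_iso = config$d_iso,
                           ratio = config$ratio, auc = cv$auc)
      }
      roc <- roc_with_ci(dec, lab, n_boot = config$n_boot,
                         seed = config$seed)
      list(model = mn, auc = roc$auc, ci = roc$ci,
           sensitivity = roc$sensitivity, specificity = roc$specificity,
           decision = dec, best = best, roc = roc)
    })
    names(out$classify) <- names(models)
    emit("roc.json", function(p) {
      js <- lapply(out$classify, function(r)
        list(auc = r$auc, ci = r$ci, sensitivity = r$sensitivity,
             specificity = r$specificity, decision = r$decision))
      jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA)
    })
  }

  out$manifest$results <- manifest_results(out)
  emit("manifest.json", function(p)
    jsonlite::write_json(out$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  out
}

config_echo <- function(config) {
  ce <- unclass(config)
  ce$spec <- unclass(ce$spec)
  ce
}

manifest_results <- function(out) {
  res <- list()
  if (!is.null(out$features))
    res$n_patients <- nrow(out$features)
  if (!is.null(out$iris))
    res$retained_embeddings <- length(out$iris$selection$index)
  if (!is.null(out$network)) {
    res$average_path_length <- out$network$paths$average_path_length
    res$diameter <- out$network$paths$diameter
    res$average_clustering <- out$network$clustering$average_clustering
    res$top_hub <- out$network$hubs$parameter[1L]
  }
  if (!is.null(out$classify))
    res$auc <- lapply(out$classify, `[[`, "auc")
  res
}

#' Group-wise feature summary with pairwise tests
#'
#' Reproduces the group-comparison report structure: per feature the
#' mean +- SD within each group and Welch two-sided t-test p-values for each
#' group pair, flagged significant at p <= 0.05 (no multiple-testing
#' correction by default; Benjamini-Hochberg optional).
#'
#' @param feature_table data.frame of numeric feature columns.
#' @param groups factor/character of group membership (>= 2 groups, each
#'   n >= 2).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame: feature, `<group>_mean`, `<group>_sd` columns, one
#'   p-value column per group pair, `significant`.
#' @export
compare_groups <- function(feature_table, groups, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  num <- vapply(feature_table, is.numeric, logical(1L))
  feats <- names(feature_table)[num]
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  rows <- lapply(feats, function(f) {
    x <- feature_table[[f]]
    row <- list(feature = f)
    for (g in lv) {
      row[[paste0(g, "_mean")]] <- mean(x[groups == g])
      row[[paste0(g, "_sd")]] <- stats::sd(x[groups == g])
    }
    for (q in seq_len(ncol(pairs))) {
      a <- x[groups == pairs[1, q]]; b <- x[groups == pairs[2, q]]
      p <- tryCatch(group_ttest(a, b), error = function(e) NA_real_)
      row[[paste("p", pairs[1, q], pairs[2, q], sep = "_")]] <- p
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pcols <- grep("^p_", names(out), value = TRUE)
  if (p_adjust == "BH")
    for (pc in pcols) out[[pc]] <- stats::p.adjust(out[[pc]], "BH")
  out$significant <- apply(out[, pcols, drop = FALSE], 1L,
                           function(p) any(p <= 0.05, na.rm = TRUE))
  out
}
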