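# End-to-end orchestration: preprocess -> two-pass segmentation -> contour
# refinement -> conditional watershed (with re-refinement of new contours) ->
# feature extraction -> optional classification; plus exploratory
# clustering/PCA of feature tables and strict config handling.

#' Default pipeline configuration
#'
#' Nested configuration for every stage. Unknown keys are rejected when
#' loading from file, so typos cannot silently fall back to defaults.
#'
#' @param preprocess,segment,refine,watershed,features stage configs.
#' @param seed RNG seed for stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            segment = twopass_config(),
                            refine = refine_config(),
                            watershed = watershed_config(),
                            features = feature_config(),
                            seed = 1L) {
  structure(list(preprocess = preprocess, segment = segment, refine = refine,
                 watershed = watershed, features = features,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; top-level keys `preprocess`, `segment`,
#'   `refine`, `watershed`, `features`, `seed` (all optional). Unknown keys
#'   at either level are rejected.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  defaults <- pipeline_config()
  builders <- list(preprocess = preprocess_config, segment = twopass_config,
                   refine = refine_config, watershed = watershed_config,
                   features = feature_config)
  bad <- setdiff(names(raw), c(names(builders), "seed"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  out <- defaults
  for (k in intersect(names(raw), names(builders))) {
    known <- names(formals(builders[[k]]))
    bad <- setdiff(names(raw[[k]]), known)
    if (length(bad))
      stop("unknown config keys under '", k, "': ", paste(bad, collapse = ", "))
    out[[k]] <- do.call(builders[[k]], raw[[k]])
  }
  if (!is.null(raw$seed)) out$seed <- as.integer(raw$seed)
  out
}

#' Run the full segmentation pipeline on one image
#'
#' Preprocessing, two-pass thresholding, optimal-path contour refinement,
#' conditional watershed with re-refinement of newly split contours, and
#' feature extraction. Deterministic given the configuration.
#'
#' @param image a [calibrated_image()].
#' @param cfg a [pipeline_config()].
#' @param classifier optional `nucleus_classifier` for predictions.
#' @param verbose log stage progress via `message()`.
#' @return list with `contours` (refined, final), `features`, `predictions`
#'   (or NULL), `lineage` (data frame mapping final contours to their seed),
#'   and `stages` (intermediate results).
#' @export
run_pipeline <- function(image, cfg = pipeline_config(), classifier = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  pre <- preprocess(image, cfg$preprocess)
  seg <- two_pass_segment(pre, cfg$segment)
  say("segmentation: %d seeds, %d initial ROIs", length(seg$seeds),
      length(seg$contours))
  refined <- lapply(seg$contours, function(ct) refine(pre, ct, cfg$refine)$contour)
  final <- list()
  lineage <- list()
  for (ct in refined) {
    parts <- conditional_split(pre, ct, cfg$watershed, refine_cfg = cfg$refine)
    for (p in parts) {
      final[[length(final) + 1]] <- p
      lineage[[length(lineage) + 1]] <-
        data.frame(final_id = p$nucleus_id, seed_id = ct$nucleus_id,
                   split = length(parts) > 1)
    }
  }
  # reassign sequential ids
  for (i in seq_along(final)) final[[i]]$nucleus_id <- i
  lineage <- if (length(lineage)) {
    ldf <- do.call(rbind, lineage); ldf$final_id <- seq_along(final); ldf
  } else data.frame(final_id = integer(0), seed_id = integer(0),
                    split = logical(0))
  say("watershed: %d final contours", length(final))
  feats <- extract_all(pre, final, cfg$features)
  preds <- NULL
  if (!is.null(classifier) && nrow(feats))
    preds <- cbind(feats["nucleus_id"], predict_nuclei(classifier, feats))
  say("pipeline done in %.1f s", as.numeric(difftime(Sys.time(), t0, "secs")))
  list(contours = final, features = feats, predictions = preds,
       lineage = lineage, stages = list(preprocessed = pre, segmentation = seg,
                                        refined = refined))
}

#' Exploratory clustering and PCA of a feature table
#'
#' Z-scores the features (constant columns dropped with a warning), builds a
#' Ward dendrogram on Manhattan distances, cuts at 2 clusters, reports the
#' best label-permutation correspondence when class labels are supplied, and
#' runs PCA with per-component variance fractions and loadings. Note Ward
#' linkage classically assumes squared Euclidean distances; the Manhattan
#' variant is used here deliberately and flagged in the report.
#'
#' @param features numeric feature data frame (>= 10 rows).
#' @param labels optional class labels.
#' @return list with `clusters`, `correspondence`, `hclust`, `pca`
#'   (`variance_fraction`, `loadings`, `scores`), `caveats`.
#' @export
explore <- function(features, labels = NULL) {
  num <- features[vapply(features, is.numeric, TRUE)]
  num <- num[setdiff(names(num), c("nucleus_id", "border_flag"))]
  if (nrow(num) < 10) stop("need at least 10 rows to explore")
  const <- vapply(num, function(x) sd(x) == 0 || !is.finite(sd(x)), TRUE)
  if (any(const)) {
    warning("dropping constant feature columns: ",
            paste(names(num)[const], collapse = ", "))
    num <- num[!const]
  }
  z <- scale(as.matrix(num))
  hc <- hclust(dist(z, method = "manhattan"), method = "ward.D")
  cl <- cutree(hc, k = 2)
  correspondence <- NA_real_
  if (!is.null(labels)) {
    lab <- as.character(labels)
    lv <- unique(lab)
    if (length(lv) == 2) {
      acc1 <- mean((cl == 1) == (lab == lv[1]))
      correspondence <- max(acc1, 1 - acc1)
    }
  }
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(clusters = cl, correspondence = correspondence, hclust = hc,
       pca = list(variance_fraction = vf, loadings = p$rotation,
                  scores = p$x),
       caveats = "Ward linkage applied to Manhattan distances (as configured), not its classical squared-Euclidean setting")
}
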