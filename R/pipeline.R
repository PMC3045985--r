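# Pipeline orchestration: register -> segment -> extract -> select ->
# evaluate over a cohort manifest, with per-stage artifacts addressed by a
# hash of the configuration that produced them (so changing an upstream
# constant invalidates every downstream cache).

#' Pipeline configuration
#'
#' @param seed master seed for evaluation partitions.
#' @param seg \code{\link{seg_config}}.
#' @param feat \code{\link{feat_config}}.
#' @param clf \code{\link{classifier_config}}.
#' @param sel \code{\link{selection_config}}.
#' @param min_epithelium samples with this many or fewer epithelial pixels
#'   in the cell-type map are excluded (the cohort must have enough
#'   epithelium for morphology to be meaningful).
#' @param registry feature registry data.frame.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1, seg = seg_config(),
                            feat = feat_config(),
                            clf = classifier_config(),
                            sel = selection_config(),
                            min_epithelium = 100,
                            registry = feature_registry()) {
  structure(list(seed = seed, seg = seg, feat = feat, clf = clf, sel = sel,
                 min_epithelium = min_epithelium, registry = registry),
            class = "pipeline_config")
}

#' Validate a pipeline configuration loaded from file
#'
#' Rejects unknown keys and checks each block against its constructor's
#' argument names.
#'
#' @param cfg list (e.g. from JSON) to merge over the defaults.
#' @return a full \code{pipeline_config}.
#' @export
validate_pipeline_config <- function(cfg) {
  base <- pipeline_config()
  unknown <- setdiff(names(cfg), names(unclass(base)))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  blocks <- list(seg = seg_config, feat = feat_config,
                 clf = classifier_config, sel = selection_config)
  for (b in names(blocks)) {
    if (is.null(cfg[[b]])) next
    bad <- setdiff(names(cfg[[b]]), names(formals(blocks[[b]])))
    if (length(bad))
      stop("unknown key(s) in config block '", b, "': ",
           paste(bad, collapse = ", "))
    base[[b]][names(cfg[[b]])] <- cfg[[b]]
  }
  for (k in setdiff(names(cfg), names(blocks))) base[[k]] <- cfg[[k]]
  base
}

# Short content hash of an R object (configuration addressing).
cfg_hash <- function(x) substr(rlang::hash(x), 1, 10)

stage_dir <- function(out_dir, stage, key) {
  d <- file.path(out_dir, paste0(stage, "-", key))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# Serialize segmentation objects to JSON (pixel sets included so the
# feature stage can resume from the artifact alone).
seg_to_json <- function(seg, path) {
  obj <- list(
    lumens = lapply(seg$lumens, function(l)
      list(pixels = l$pixels, complete = l$complete)),
    nuclei = lapply(seg$nuclei, function(x)
      list(pixels = x$pixels, mean_intensity = x$mean_intensity)),
    epithelium = which(seg$epithelium_mask$mask) - 1L,
    tissue = which(seg$tissue_mask$mask) - 1L,
    shape = dim(seg$epithelium_mask$mask),
    circle = seg$tissue_circle)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

seg_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(x$shape)
  unflat <- function(i) {
    m <- matrix(FALSE, shape[1], shape[2])
    m[as.integer(i) + 1L] <- TRUE
    m
  }
  structure(list(
    lumens = lapply(x$lumens, function(l)
      lumen_object(matrix(unlist(l$pixels), ncol = 2), l$complete)),
    nuclei = lapply(x$nuclei, function(nu)
      nucleus_object(matrix(unlist(nu$pixels), ncol = 2),
                     nu$mean_intensity)),
    epithelium_mask = binary_mask(unflat(x$epithelium)),
    tissue_mask = binary_mask(unflat(x$tissue)),
    tissue_circle = list(center = as.numeric(x$circle$center),
                         radius = as.numeric(x$circle$radius)),
    registration = NULL), class = "segmentation_result")
}

#' Run the full pipeline over a cohort
#'
#' Per sample: registration (params JSON), segmentation (object table
#' JSON), feature extraction (cohort CSV); then nested-selection
#' cross-validation over the cohort. Every stage writes its artifacts into
#' a directory keyed by a hash of the configuration it depends on
#' (including upstream hashes), and is skipped when the artifact already
#' exists. Samples with insufficient epithelium are excluded with a reason
#' code recorded in \code{exclusions.csv}.
#'
#' @param manifest path to a cohort manifest CSV, or the data.frame
#'   itself (paths then taken as absolute).
#' @param config \code{\link{pipeline_config}}.
#' @param out_dir artifact directory.
#' @param evaluate run the cross-validated evaluation (needs both classes).
#' @return list: \code{features} (data.frame), \code{report}
#'   (\code{eval_report} or NULL), \code{exclusions} (data.frame),
#'   \code{stage_dirs}.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir,
                         evaluate = TRUE) {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reg_key <- cfg_hash(list(stage = "register",
                           white_threshold = config$seg$white_threshold))
  seg_key <- cfg_hash(list(stage = "segment", cfg = config$seg,
                           up = reg_key))
  ext_key <- cfg_hash(list(stage = "extract", cfg = config$feat,
                           registry = config$registry, up = seg_key))
  d_reg <- stage_dir(out_dir, "register", reg_key)
  d_seg <- stage_dir(out_dir, "segment", seg_key)
  d_ext <- stage_dir(out_dir, "extract", ext_key)

  exclusions <- data.frame(sample_id = character(0), reason = character(0))
  fvs <- list(); labels <- numeric(0)
  feat_csv <- file.path(d_ext, "features.csv")
  if (file.exists(feat_csv)) {
    df <- read.csv(feat_csv, check.names = FALSE)
    exc_csv <- file.path(d_ext, "exclusions.csv")
    if (file.exists(exc_csv)) exclusions <- read.csv(exc_csv)
  } else {
    for (i in seq_len(nrow(m))) {
      id <- m$sample_id[i]
      pair <- read_sample_pair(m$he_path[i], m$ir_path[i], sample_id = id,
                               class_label = m$label[i])
      n_epi <- sum(pair$ir$labels == IR_LABELS[["epithelium"]])
      if (n_epi <= config$min_epithelium) {
        exclusions <- rbind(exclusions, data.frame(
          sample_id = id, reason = "insufficient_epithelium"))
        next
      }
      # registration artifact
      reg_path <- file.path(d_reg, paste0(id, ".json"))
      if (file.exists(reg_path)) {
        rj <- jsonlite::read_json(reg_path, simplifyVector = TRUE)
        reg <- structure(list(params = affine_params(rj$tx, rj$ty,
                                                     rj$theta, rj$s),
                              objective = rj$objective,
                              n_evaluations = rj$n_evaluations),
                         class = "registration_result")
      } else {
        reg <- register_pair(pair, config$seg$white_threshold)
        jsonlite::write_json(list(tx = reg$params$tx, ty = reg$params$ty,
                                  theta = reg$params$theta,
                                  s = reg$params$s,
                                  objective = reg$objective,
                                  n_evaluations = reg$n_evaluations),
                             reg_path, auto_unbox = TRUE, digits = NA)
      }
      # segmentation artifact
      seg_path <- file.path(d_seg, paste0(id, ".json"))
      if (file.exists(seg_path)) {
        seg <- seg_from_json(seg_path)
      } else {
        seg <- segment_sample(pair, reg, config$seg)
        seg_to_json(seg, seg_path)
      }
      fv <- extract_features(seg, pair$he, config$registry, config$feat,
                             sample_id = id)
      fvs[[length(fvs) + 1L]] <- fv
      labels <- c(labels, m$label[i])
    }
    if (length(fvs) == 0L) stop("run_pipeline: all samples excluded")
    df <- feature_table(fvs, labels)
    write.csv(df, feat_csv, row.names = FALSE)
    write.csv(exclusions, file.path(d_ext, "exclusions.csv"),
              row.names = FALSE)
  }

  report <- NULL
  if (evaluate && length(unique(df$label)) == 2L) {
    X <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")),
                      drop = FALSE])
    cfg <- config$clf
    cfg$seed <- config$seed
    eval_key <- cfg_hash(list(stage = "evaluate", clf = cfg,
                              sel = config$sel, up = ext_key))
    d_eval <- stage_dir(out_dir, "evaluate", eval_key)
    report <- cross_validate(X, df$label, cfg, config$sel)
    jsonlite::write_json(
      list(auc_mean = report$auc_mean, auc_sd = report$auc_sd,
           spec_at_sens = report$spec_at_sens,
           n_folds = report$n_folds, n_repeats = report$n_repeats,
           config_hash = eval_key, seed = config$seed),
      file.path(d_eval, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(features = df, report = report, exclusions = exclusions,
       stage_dirs = list(register = d_reg, segment = d_seg,
                         extract = d_ext))
}
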