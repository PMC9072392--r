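# End-to-end driver: simulate or load images -> select ROIs -> orientation
# index + FOS + SOS per ROI -> group comparisons -> CSV/JSON outputs.
#
# Every stochastic step draws from a seed derived deterministically from the
# run seed, so a rerun with the same config is byte-identical.

.feature_columns <- c("oi", "fos_mean", "fos_std", "fos_skewness",
                      "fos_kurtosis", "sos_energy", "sos_inertia",
                      "sos_correlation", "sos_idm", "sos_entropy")

#' Build a pipeline run configuration
#'
#' Collects every tunable parameter of the analysis into one validated
#' list. Exactly one of \code{simulation} or \code{manifest} must be given:
#' \code{simulation} is a named list of groups, each a list of arguments for
#' \code{\link{generate_fiber_image}} plus \code{n_images};
#' \code{manifest} is a data frame with columns \code{path}, \code{group}
#' and optionally \code{mask_path} (vessel lumen mask image).
#'
#' @param simulation named list of per-group simulation specs, or
#'   \code{NULL}.
#' @param manifest data frame of input images, or \code{NULL}.
#' @param pixel_size_um fallback pixel size for manifest images without
#'   metadata.
#' @param roi list of ROI parameters: \code{side_um}, \code{max_distance_um},
#'   \code{min_count}, \code{max_count}, \code{whole_image}.
#' @param fft list: \code{threshold}, \code{window}.
#' @param glcm list: \code{n_levels}, \code{distance_px}, \code{directions},
#'   \code{symmetric}.
#' @param stars list: \code{mode} ("vs-control" or "all-pairs"),
#'   \code{control} group label, \code{thresholds}.
#' @param seed mandatory integer seed for every stochastic step.
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(simulation = NULL, manifest = NULL,
                       pixel_size_um = 0.15,
                       roi = list(), fft = list(), glcm = list(),
                       stars = list(), seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (is.null(simulation) == is.null(manifest))
    stop("give exactly one of 'simulation' or 'manifest'", call. = FALSE)
  if (!is.null(manifest)) {
    manifest <- as.data.frame(manifest)
    if (!all(c("path", "group") %in% names(manifest)))
      stop("'manifest' needs columns 'path' and 'group'", call. = FALSE)
    missing_files <- manifest$path[!file.exists(manifest$path)]
    if (length(missing_files) > 0)
      stop("unreadable input image(s): ",
           paste(missing_files, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    simulation = simulation,
    manifest = manifest,
    pixel_size_um = pixel_size_um,
    roi = utils::modifyList(list(side_um = 150, max_distance_um = 500,
                                 min_count = 50, max_count = 80,
                                 whole_image = TRUE), roi),
    fft = utils::modifyList(list(threshold = 0.38, window = TRUE), fft),
    glcm = utils::modifyList(list(n_levels = 64, distance_px = 1,
                                  directions = c(0, 45, 90, 135),
                                  symmetric = TRUE), glcm),
    stars = utils::modifyList(list(mode = "vs-control", control = NULL,
                                   thresholds = c(0.1, 0.01, 0.001)), stars),
    seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} needs the
#'   \pkg{yaml} package; \code{.json} uses \pkg{jsonlite}).
#' @param seed optional seed overriding the file's.
#' @return A \code{run_config}.
#' @export
read_config <- function(path, seed = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", path, call. = FALSE)
  raw$seed <- seed %||% raw$seed
  if (!is.null(raw$manifest)) raw$manifest <- as.data.frame(raw$manifest)
  do.call(run_config, raw)
}

# deterministic per-image sub-seed, kept within 32-bit integer range
.derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + index * 2246822519 + salt * 2654435761)
             %% 2147483647)
}

#' Run the full SHG analysis pipeline
#'
#' Simulates (or loads) the configured images, selects ROIs, computes the
#' orientation index, first-order statistics and GLCM features for every
#' ROI, compares every feature between the configured group pairs, and —
#' when \code{out_dir} is given — writes \code{features.csv},
#' \code{comparisons.csv} and \code{run_log.json}, each stamped with the
#' configuration hash. Degenerate (constant-intensity) ROIs stay in the
#' feature table with missing OI/skewness/kurtosis and are dropped pairwise
#' from the statistics; their count is logged.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory, created if needed.
#' @return An object of class \code{shg_run}: list with data frames
#'   \code{features} and \code{comparisons}, and a \code{log} list
#'   (package version, config hash, seed, per-image ROI counts, warnings).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))
  log <- list(package = "shgtex",
              version = as.character(utils::packageVersion("shgtex")),
              config_hash = hash, seed = config$seed,
              images = list(), warnings = character(0),
              n_degenerate_rois = 0L)

  images <- .load_or_simulate(config)
  feat_rows <- list()
  for (k in seq_along(images)) {
    item <- images[[k]]
    roi_seed <- .derive_seed(config$seed, k, salt = 1L)
    rs <- withCallingHandlers(
      select_rois(item$image, vessel_mask = item$vessel_mask,
                  side_um = config$roi$side_um,
                  max_distance_um = config$roi$max_distance_um,
                  min_count = config$roi$min_count,
                  max_count = config$roi$max_count,
                  seed = roi_seed,
                  whole_image = config$roi$whole_image),
      warning = function(w) {
        log$warnings <<- c(log$warnings,
                           sprintf("%s: %s", item$id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    log$images[[item$id]] <- list(group = item$group, n_rois = nrow(rs$rois))
    for (j in seq_len(nrow(rs$rois))) {
      roi <- rs$rois[j, ]
      patch <- extract_roi(item$image, roi)
      feat_rows[[length(feat_rows) + 1]] <-
        .roi_features(patch, roi, item, config)
    }
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  n_deg <- sum(features$degenerate)
  log$n_degenerate_rois <- n_deg
  if (n_deg > 0)
    log$warnings <- c(log$warnings,
                      sprintf("%d degenerate ROI(s) kept with missing OI",
                              n_deg))

  comparisons <- if (length(unique(features$group)) > 1) {
    compare_all_groups(features, .feature_columns,
                       mode = config$stars$mode,
                       control = config$stars$control,
                       star_thresholds = config$stars$thresholds,
                       strict = FALSE)
  } else {
    data.frame(feature = character(0), group_a = character(0),
               group_b = character(0), n_a = integer(0), n_b = integer(0),
               n_dropped = integer(0), t_statistic = numeric(0),
               df = integer(0), p_value = numeric(0), stars = character(0),
               stringsAsFactors = FALSE)
  }

  run <- structure(list(features = features, comparisons = comparisons,
                        log = log, config = config),
                   class = "shg_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(features, file.path(out_dir, "features.csv"), hash,
                config$seed)
    write_table(comparisons, file.path(out_dir, "comparisons.csv"), hash,
                config$seed)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

.load_or_simulate <- function(config) {
  images <- list()
  if (!is.null(config$simulation)) {
    idx <- 0L
    for (gname in names(config$simulation)) {
      spec <- config$simulation[[gname]]
      n_images <- spec$n_images %||% 1L
      spec$n_images <- NULL
      for (i in seq_len(n_images)) {
        idx <- idx + 1L
        spec_i <- spec
        spec_i$seed <- .derive_seed(config$seed, idx)
        gen <- spec_i$generator %||% "fibers"
        spec_i$generator <- NULL
        sc <- if (identical(gen, "vessel")) {
          do.call(generate_vessel_scene, spec_i)
        } else do.call(generate_fiber_image, spec_i)
        images[[idx]] <- list(id = sprintf("%s_img%02d", gname, i),
                              group = gname, image = sc$image,
                              vessel_mask = sc$truth$vessel_mask,
                              truth = sc$truth)
      }
    }
  } else {
    man <- config$manifest
    for (i in seq_len(nrow(man))) {
      img <- read_image(man$path[i], pixel_size_um = config$pixel_size_um)
      mask <- NULL
      if (!is.null(man$mask_path) && !is.na(man$mask_path[i]) &&
          nzchar(man$mask_path[i])) {
        mask <- read_image(man$mask_path[i],
                           pixel_size_um = config$pixel_size_um)$pixels > 0
      }
      images[[i]] <- list(id = basename(man$path[i]), group = man$group[i],
                          image = img, vessel_mask = mask, truth = NULL)
    }
    px_by_group <- tapply(
      vapply(images, function(x) x$image$pixel_size_um, numeric(1)),
      vapply(images, function(x) x$group, character(1)),
      function(v) length(unique(v)))
    if (any(px_by_group > 1))
      stop("inconsistent pixel sizes within a group", call. = FALSE)
  }
  images
}

# one FeatureRecord row
.roi_features <- function(patch, roi, item, config) {
  ax <- orientation_index(patch, threshold = config$fft$threshold,
                          window = config$fft$window)
  fos <- fos_features(patch)
  g <- compute_glcm(patch, n_levels = config$glcm$n_levels,
                    distance_px = config$glcm$distance_px,
                    directions = config$glcm$directions,
                    symmetric = config$glcm$symmetric)
  sos <- sos_features(g)
  data.frame(
    roi_id = paste(item$id, roi$id, sep = "_"),
    image_id = item$id, group = item$group,
    row = roi$row, col = roi$col, side_px = roi$side_px,
    vessel_distance_um = roi$vessel_distance_um,
    degenerate = isTRUE(ax$degenerate),
    oi = ax$oi,
    fos_mean = fos$mean, fos_std = fos$std,
    fos_skewness = fos$skewness, fos_kurtosis = fos$kurtosis,
    sos_energy = sos$energy, sos_inertia = sos$inertia,
    sos_correlation = sos$correlation, sos_idm = sos$idm,
    sos_entropy = sos$entropy,
    stringsAsFactors = FALSE)
}

#' Write a pipeline table as CSV with a provenance header
#'
#' The first line is a comment carrying the package version, configuration
#' hash and seed; the rest is a standard CSV with a stable column order.
#' Read back with \code{read.csv(path, comment.char = "#")}.
#'
#' @param rows data frame.
#' @param path output path.
#' @param hash configuration hash string.
#' @param seed run seed.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path, hash = "", seed = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# shgtex %s; config_hash=%s; seed=%s",
                     as.character(utils::packageVersion("shgtex")),
                     hash, format(seed)), con)
  utils::write.table(rows, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @export
print.shg_run <- function(x, ...) {
  cat(sprintf("<shg_run> %d ROIs from %d image(s), %d group(s)\n",
              nrow(x$features), length(x$log$images),
              length(unique(x$features$group))))
  cat(sprintf("  config %s, seed %d; %d comparison row(s)\n",
              x$log$config_hash, x$log$seed, nrow(x$comparisons)))
  sig <- x$comparisons[!is.na(x$comparisons$stars) &
                         x$comparisons$stars != "", , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("  significant (starred) comparisons:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-16s %s vs %s  p = %.3g %s\n", sig$feature[i],
                  sig$group_a[i], sig$group_b[i], sig$p_value[i],
                  sig$stars[i]))
  }
  for (w in x$log$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.shg_run <- function(object, ...) {
  feats <- .feature_columns
  groups <- unique(object$features$group)
  rows <- list()
  for (f in feats) for (g in groups) {
    v <- object$features[[f]][object$features$group == g]
    if (!any(is.finite(v))) next
    b <- box_summary(v)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, group = g, n = b$n, median = b$median,
      q25 = b$q25, q75 = b$q75,
      whisker_low = b$whisker_low, whisker_high = b$whisker_high,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.shg_run", "data.frame")
  out
}

#' @export
print.summary.shg_run <- function(x, ...) {
  cat("Per-group box summaries (median [q25, q75]):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.shg_run <- function(x, features = c("oi", "fos_mean", "sos_entropy"),
                         ...) {
  features <- intersect(features, names(x$features))
  old <- par(mfrow = c(1, length(features)))
  on.exit(par(old))
  for (f in features) {
    boxplot(x$features[[f]] ~ factor(x$features$group), range = 1.5,
            xlab = "group", ylab = f, main = f, ...)
  }
  invisible(x)
}
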