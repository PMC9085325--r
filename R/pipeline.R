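#' Read a labels table and its images
#'
#' The labels table is a TSV with columns `path` (image file, relative to the
#' table's directory or absolute) and `label`.
#'
#' @param labels_tsv Path to the labels TSV.
#' @return List with `images` (list of gray-image matrices), `labels`
#'   (character) and `paths`.
#' @export
read_labeled_images <- function(labels_tsv) {
  if (!file.exists(labels_tsv)) {
    stop_domain("labels table not found: ", labels_tsv)
  }
  df <- utils::read.delim(labels_tsv, colClasses = "character")
  if (!all(c("path", "label") %in% names(df))) {
    stop_domain("labels table must have columns 'path' and 'label': ",
                labels_tsv)
  }
  base <- dirname(labels_tsv)
  paths <- ifelse(file.exists(df$path), df$path, file.path(base, df$path))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_domain("image file not found: ", paths[which(missing)[1]])
  }
  list(images = lapply(paths, read_gray_image), labels = df$label,
       paths = paths)
}

#' Run the end-to-end pipeline and write its artifacts
#'
#' Executes optional preprocessing, quantization, n-gram extraction,
#' weighting, two-step selection and cross-validated classification on a
#' labeled image set, then writes to `out_dir`:
#' `report.json` (the cross-validation report), `roc.csv` (pooled ROC points,
#' binary task), `selection.tsv` (audit of a final selection fit on the full
#' dataset), the feature store (`features.mtx` + vocabulary TSV + document
#' ids) and `manifest.json` (config, seed, package version).
#'
#' @param labels_tsv Labels TSV (columns `path`, `label`); or a
#'   `synthetic_dataset` in place of files on disk.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return The `cv_report`, invisibly.
#' @export
run_pipeline <- function(labels_tsv, config = pipeline_config(),
                         out_dir = "ngramimg_out") {
  if (inherits(labels_tsv, "synthetic_dataset")) {
    images <- labels_tsv$images
    labels <- labels_tsv$labels
  } else {
    dat <- read_labeled_images(labels_tsv)
    images <- dat$images
    labels <- dat$labels
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- cross_validate(images, labels, config = config)

  # audit artifacts from a fit on the full dataset (the CV report itself only
  # uses per-fold fits)
  docs <- tokenize_images(images, orders = config$orders)
  vocab <- build_vocabulary(docs)
  counts <- count_matrix(vocab, docs)
  classes <- sort(unique(labels))
  if (length(classes) == 2) {
    X <- if (config$weighting == "tf_rf") {
      tf_rf(counts, labels, classes[1], per_order = config$per_order_tf)
    } else {
      tf(counts, per_order = config$per_order_tf)
    }
    sel <- select_features(X, labels, alpha = config$alpha,
                           fraction = config$fraction, adjust = config$adjust)
    write_selection(sel, vocab, file.path(out_dir, "selection.tsv"))
    write_feature_store(X, vocab, file.path(out_dir, "features"))
  } else {
    write_feature_store(tf(counts, per_order = config$per_order_tf), vocab,
                        file.path(out_dir, "features"))
  }

  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (report$task == "binary") {
    utils::write.table(report$roc, file.path(out_dir, "roc.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = config_to_list(config),
         seed = config$seed,
         package = "ngramimg",
         version = as.character(utils::packageVersion("ngramimg"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(report)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$classifier <- unclass(out$classifier)
  out
}

report_to_list <- function(report) {
  out <- unclass(report)
  out$config <- config_to_list(out$config)
  if (report$task == "binary") {
    out$roc <- NULL  # written separately as CSV
  }
  out
}
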