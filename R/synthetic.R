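#' Specify a synthetic image class
#'
#' A synthetic class is defined by background quantization bins and a short
#' horizontal gray-level motif planted into rows at a given rate. Background
#' pixels are drawn i.i.d. uniform over the union of the background bins' gray
#' ranges, which keeps the null token distribution exchangeable across classes
#' so downstream selection tests stay calibrated; motifs are runs of 2-3
#' consecutive pixels whose gray values fall in the motif's bins, which the
#' row-wise extractor sees as class-specific tokens.
#'
#' @param label Class identifier (character scalar).
#' @param background_bins Integer vector of quantization-bin indices (0--15)
#'   for background noise.
#' @param motif Integer vector of 2 or 3 bin indices planted as a horizontal
#'   run.
#' @param motif_rate Expected number of planted motifs per image row (>= 0);
#'   per-row counts are Poisson.
#' @return A `class_spec` object.
#' @export
class_spec <- function(label, background_bins, motif, motif_rate = 1) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    stop_domain("label must be a non-empty string")
  }
  background_bins <- as.integer(background_bins)
  motif <- as.integer(motif)
  if (length(background_bins) == 0 ||
      any(background_bins < 0 | background_bins > 15)) {
    stop_domain("background_bins must be bin indices in 0:15")
  }
  if (!length(motif) %in% 2:3 || any(motif < 0 | motif > 15)) {
    stop_domain("motif must be 2 or 3 bin indices in 0:15")
  }
  if (!is.numeric(motif_rate) || motif_rate < 0) {
    stop_domain("motif_rate must be >= 0")
  }
  structure(
    list(label = label, background_bins = background_bins,
         motif = motif, motif_rate = motif_rate),
    class = "class_spec"
  )
}

# All row-wise n-gram windows (orders 1..3) of a motif's letter string: the
# tokens the motif is guaranteed to plant.
motif_tokens <- function(motif, orders = c(1L, 2L, 3L)) {
  letters16 <- quant_alphabet()[motif + 1]
  s <- paste0(letters16, collapse = "")
  w <- length(letters16)
  out <- character(0)
  for (n in check_orders(orders)) {
    if (w < n) next
    starts <- seq_len(w - n + 1L)
    out <- c(out, substring(s, starts, starts + n - 1L))
  }
  unique(out)
}

# Draw a uniform gray value inside each requested bin (bin b covers
# 16 b .. 16 b + 15).
gray_in_bins <- function(bins, n) {
  b <- if (length(bins) == 1) rep.int(bins, n) else sample(bins, n, replace = TRUE)
  as.integer(b * 16L + sample.int(16L, n, replace = TRUE) - 1L)
}

#' Generate one synthetic gray image
#'
#' Fills the image with background noise drawn uniformly within the gray
#' ranges of the class's background bins, then plants motifs: for each row,
#' a Poisson(`motif_rate`) number of motifs at uniformly random, non-wrapping
#' start columns, each motif pixel drawn uniformly within its bin's gray range.
#' Rows are treated independently, matching the row-wise token-extraction
#' geometry. Identical `(spec, height, width, seed)` give identical images.
#'
#' @param spec A [class_spec()].
#' @param height,width Image dimensions in pixels; `width` must be at least the
#'   motif length.
#' @param seed Integer seed.
#' @return Integer gray-image matrix (`height` x `width`, values in 0--255).
#' @export
make_image <- function(spec, height = 32, width = 32, seed = 1) {
  stopifnot(inherits(spec, "class_spec"))
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || height < 1) stop_domain("height must be >= 1")
  if (is.na(width) || width < length(spec$motif)) {
    stop_domain("width must be at least the motif length")
  }
  with_seed(seed, {
    img <- matrix(gray_in_bins(spec$background_bins, height * width),
                  nrow = height, ncol = width)
    if (spec$motif_rate > 0) {
      len <- length(spec$motif)
      for (r in seq_len(height)) {
        k <- stats::rpois(1, spec$motif_rate)
        if (k == 0) next
        for (m in seq_len(k)) {
          start <- sample.int(width - len + 1L, 1L)
          img[r, start:(start + len - 1L)] <-
            vapply(spec$motif, function(b) gray_in_bins(b, 1L), integer(1))
        }
      }
    }
    img
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_per_class` images for each class spec (a vector gives per-class
#' counts, supporting class imbalance), with labels and the per-class truth
#' tokens — the letter-string windows of each motif, i.e. exactly the tokens
#' the generator plants. Identical arguments give byte-identical datasets.
#'
#' @param specs List of [class_spec()] with distinct labels (>= 2).
#' @param n_per_class Images per class; scalar or one count per spec.
#' @param shape Image dimensions `c(height, width)`.
#' @param seed Integer seed; per-image seeds are derived from it.
#' @param orders N-gram orders used to enumerate truth tokens.
#' @return A `synthetic_dataset`: list with `images`, `labels`,
#'   `truth_tokens` (named list per class), `specs`, `shape`, `seed`.
#' @export
make_dataset <- function(specs, n_per_class, shape = c(32, 32), seed = 1,
                         orders = c(1L, 2L, 3L)) {
  if (length(specs) < 2) stop_domain("need at least two class specs")
  stopifnot(all(vapply(specs, inherits, logical(1), "class_spec")))
  labs <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop_domain("class labels must be distinct")
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, length(specs))
  if (length(n_per_class) != length(specs) || any(n_per_class < 1)) {
    stop_domain("n_per_class must be a positive count per class")
  }
  total <- sum(n_per_class)
  iseeds <- derive_seeds(seed, total)
  images <- vector("list", total)
  labels <- character(total)
  k <- 0L
  for (s in seq_along(specs)) {
    for (i in seq_len(n_per_class[s])) {
      k <- k + 1L
      images[[k]] <- make_image(specs[[s]], shape[1], shape[2], iseeds[k])
      labels[k] <- labs[s]
    }
  }
  truth <- lapply(specs, function(sp) motif_tokens(sp$motif, orders))
  names(truth) <- labs
  structure(
    list(images = images, labels = labels, truth_tokens = truth,
         specs = specs, shape = as.integer(shape), seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$images), "images (",
      paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
            collapse = ", "),
      "),", x$shape[1], "x", x$shape[2], "\n")
  invisible(x)
}

#' Default demonstration class specs
#'
#' Two or three classes sharing low-intensity background bins 0--7 (letters
#' A--H) with disjoint bright motifs: `classA` plants `JKL` (bins 9, 10, 11),
#' `classB` plants `NOP` (bins 13, 14, 15) and `classC` plants `IMI`
#' (bins 8, 12, 8), one expected motif per row. Because the motif bins never
#' occur in the background, every truth token is exclusive to its class.
#'
#' @param n_classes 2 or 3.
#' @param motif_rate Expected motifs per row.
#' @return List of [class_spec()].
#' @export
demo_class_specs <- function(n_classes = 2, motif_rate = 1) {
  if (!n_classes %in% 2:3) stop_domain("n_classes must be 2 or 3")
  specs <- list(
    class_spec("classA", background_bins = 0:7, motif = c(9L, 10L, 11L),
               motif_rate = motif_rate),
    class_spec("classB", background_bins = 0:7, motif = c(13L, 14L, 15L),
               motif_rate = motif_rate),
    class_spec("classC", background_bins = 0:7, motif = c(8L, 12L, 8L),
               motif_rate = motif_rate)
  )
  specs[seq_len(n_classes)]
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per image into per-class subdirectories, a `labels.tsv`
#' (columns `path`, `label`) and a `truth_tokens.json` manifest.
#'
#' @param ds A [make_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$images))
  counter <- stats::setNames(rep(0L, length(unique(ds$labels))),
                             unique(ds$labels))
  for (i in seq_along(ds$images)) {
    lab <- ds$labels[i]
    counter[lab] <- counter[lab] + 1L
    sub <- file.path(dir, lab)
    dir.create(sub, showWarnings = FALSE)
    paths[i] <- file.path(lab, sprintf("%s_%03d.png", lab, counter[lab]))
    write_gray_image(ds$images[[i]], file.path(dir, paths[i]))
  }
  utils::write.table(data.frame(path = paths, label = ds$labels),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth_tokens, file.path(dir, "truth_tokens.json"))
  invisible(dir)
}
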