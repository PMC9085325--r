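#' Letter alphabet of the 16-level quantization
#'
#' The sixteen letters `A` through `P` used to re-express gray values. Each
#' letter covers one 16-wide integer intensity bin: `A` = gray 0--15,
#' `B` = 16--31, ..., `P` = 240--255.
#'
#' @return Character vector of length 16.
#' @export
quant_alphabet <- function() LETTERS[1:16]

#' Map gray values to quantization letters
#'
#' Assigns each integer gray value in \[0, 255\] to one of 16 letters by its
#' 16-wide intensity bin: letter index is `floor(value / 16)`, so 0--15 map to
#' `A` and 240--255 map to `P`. The mapping is monotone non-decreasing in the
#' gray value.
#'
#' @param gray_value Integer vector with values in \[0, 255\]. Non-integer
#'   values are rejected rather than rounded: the partition is defined on
#'   integer gray levels.
#' @return Character vector of single letters in `A`--`P`.
#' @examples
#' letter_of(c(0, 15, 16, 204, 255))
#' @export
letter_of <- function(gray_value) {
  if (length(gray_value) == 0) return(character(0))
  if (!is.numeric(gray_value) || anyNA(gray_value)) {
    stop_domain("gray values must be non-missing numerics")
  }
  if (any(gray_value != floor(gray_value))) {
    stop_domain("gray values must be integers; got non-integer input")
  }
  if (any(gray_value < 0 | gray_value > 255)) {
    stop_domain("gray values must lie in [0, 255]")
  }
  quant_alphabet()[gray_value %/% 16 + 1]
}

#' Quantize a gray image into a character matrix
#'
#' Applies [letter_of()] elementwise, turning a gray-value matrix into a
#' same-shaped matrix over the 16-letter alphabet. This is the point-by-point
#' conversion from image to "text" on which all n-gram extraction operates.
#'
#' @param img Integer matrix with values in \[0, 255\] (a gray image).
#' @return Character matrix of identical shape; entries are letters `A`--`P`.
#' @examples
#' quantize(matrix(c(0, 100, 200, 255), 2, 2))
#' @export
quantize <- function(img) {
  check_gray_image(img)
  matrix(letter_of(as.vector(img)), nrow = nrow(img), ncol = ncol(img))
}

check_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_domain("a gray image must be a numeric matrix")
  }
  if (nrow(img) < 1 || ncol(img) < 1) stop_domain("a gray image must be non-empty")
  if (anyNA(img)) stop_domain("a gray image must not contain missing values")
  if (any(img != floor(img))) stop_domain("gray values must be integers")
  if (any(img < 0 | img > 255)) stop_domain("gray values must lie in [0, 255]")
  invisible(img)
}

check_char_matrix <- function(cm) {
  if (!is.matrix(cm) || !is.character(cm)) {
    stop_domain("a character matrix must be a matrix of single letters")
  }
  if (!all(cm %in% quant_alphabet())) {
    stop_domain("character-matrix entries must be letters A-P")
  }
  invisible(cm)
}

#' Write/read a character matrix as plain text
#'
#' Debug serialization: one image row per line, letters concatenated without
#' separators.
#'
#' @param cm Character matrix (see [quantize()]).
#' @param path File path.
#' @return `write_char_matrix()` returns `path` invisibly; `read_char_matrix()`
#'   returns the character matrix.
#' @export
write_char_matrix <- function(cm, path) {
  check_char_matrix(cm)
  writeLines(apply(cm, 1, paste0, collapse = ""), path)
  invisible(path)
}

#' @rdname write_char_matrix
#' @export
read_char_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop_domain("empty character-matrix file: ", path)
  cm <- do.call(rbind, strsplit(lines, "", fixed = TRUE))
  check_char_matrix(cm)
  cm
}
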