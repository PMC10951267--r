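# Built-in sans-serif bitmap glyphs, lowercase a-z, on a 5 x 9 cell grid:
# rows 1-2 ascender zone, rows 3-7 the x-height zone, rows 8-9 descenders.
# The font is a package-authored face with configurable metrics; glyph
# proportions are scaled at render time so that a five-letter word spans the
# configured width and the x-height zone spans the configured height.
GLYPHS_5x9 <- c(
  a = ".....|.....|.###.|....#|.####|#...#|.####|.....|.....",
  b = "#....|#....|####.|#...#|#...#|#...#|####.|.....|.....",
  c = ".....|.....|.####|#....|#....|#....|.####|.....|.....",
  d = "....#|....#|.####|#...#|#...#|#...#|.####|.....|.....",
  e = ".....|.....|.###.|#...#|#####|#....|.###.|.....|.....",
  f = "..##.|.#...|####.|.#...|.#...|.#...|.#...|.....|.....",
  g = ".....|.....|.####|#...#|#...#|#...#|.####|....#|.###.",
  h = "#....|#....|####.|#...#|#...#|#...#|#...#|.....|.....",
  i = "..#..|.....|.##..|..#..|..#..|..#..|.###.|.....|.....",
  j = "...#.|.....|..##.|...#.|...#.|...#.|...#.|#..#.|.##..",
  k = "#....|#....|#..#.|#.#..|##...|#.#..|#..#.|.....|.....",
  l = ".##..|..#..|..#..|..#..|..#..|..#..|.###.|.....|.....",
  m = ".....|.....|##.#.|#.#.#|#.#.#|#.#.#|#.#.#|.....|.....",
  n = ".....|.....|####.|#...#|#...#|#...#|#...#|.....|.....",
  o = ".....|.....|.###.|#...#|#...#|#...#|.###.|.....|.....",
  p = ".....|.....|####.|#...#|#...#|#...#|####.|#....|#....",
  q = ".....|.....|.####|#...#|#...#|#...#|.####|....#|....#",
  r = ".....|.....|#.##.|##..#|#....|#....|#....|.....|.....",
  s = ".....|.....|.####|#....|.###.|....#|####.|.....|.....",
  t = ".#...|.#...|####.|.#...|.#...|.#...|..##.|.....|.....",
  u = ".....|.....|#...#|#...#|#...#|#...#|.####|.....|.....",
  v = ".....|.....|#...#|#...#|#...#|.#.#.|..#..|.....|.....",
  w = ".....|.....|#.#.#|#.#.#|#.#.#|#.#.#|.#.#.|.....|.....",
  x = ".....|.....|#...#|.#.#.|..#..|.#.#.|#...#|.....|.....",
  y = ".....|.....|#...#|#...#|#...#|#...#|.####|....#|.###.",
  z = ".....|.....|#####|...#.|..#..|.#...|#####|.....|....."
)

glyph_matrix <- function(ch) {
  s <- GLYPHS_5x9[[ch]]
  if (is.null(s)) abort(paste0("unrenderable character: '", ch, "'"))
  rows <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(rows) != 9 || any(nchar(rows) != 5)) {
    abort(paste0("corrupt glyph data for '", ch, "'"))
  }
  do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
}

#' Render a five-letter word as a luminance image
#'
#' Draws the word in dark ink on a light field, centered within the square
#' stimulation area (8.9 x 8.9 deg). Glyphs come from the package's built-in
#' sans-serif bitmap face; metrics are configurable and default to a
#' horizontal ink extent of 3.4 deg and an x-height of 0.75 deg, matching the
#' display geometry of the word-recognition paradigm. Rendering is
#' deterministic: the same word and metrics always give the same pixels.
#'
#' @param word A 5-letter lowercase word (a-z only).
#' @param px_per_deg Pixels per degree of visual angle (default 32).
#' @param width_deg Horizontal ink extent of the word in degrees.
#' @param x_height_deg Height of the x-height zone in degrees.
#' @param ink,paper Luminance of glyph ink and background (defaults 0 and 1).
#' @return A `luminance_image` of the stimulation area.
#' @export
#' @examples
#' img <- render_word_image("achat")
#' dim(img)
render_word_image <- function(word, px_per_deg = 32, width_deg = 3.4,
                              x_height_deg = 0.75, ink = 0, paper = 1) {
  stopifnot(is.character(word), length(word) == 1, px_per_deg > 0)
  if (nchar(word) != 5) {
    abort(paste0("word must have exactly 5 letters, got '", word, "' (", nchar(word), ")"))
  }
  letters_vec <- strsplit(tolower(word), "")[[1]]
  bad <- setdiff(letters_vec, names(GLYPHS_5x9))
  if (length(bad)) abort(paste0("unrenderable character: '", bad[1], "'"))

  # Word grid: 5 glyph columns per letter + 1 gap column between letters.
  n_let <- length(letters_vec)
  grid_cols <- 5L * n_let + (n_let - 1L)
  grid_rows <- 9L
  grid <- matrix(FALSE, grid_rows, grid_cols)
  for (i in seq_len(n_let)) {
    c0 <- (i - 1L) * 6L
    grid[, (c0 + 1L):(c0 + 5L)] <- glyph_matrix(letters_vec[i])
  }

  col_w_deg <- width_deg / grid_cols
  row_h_deg <- x_height_deg / 5 # five rows span the x-height zone
  word_w_px <- width_deg * px_per_deg
  word_h_px <- grid_rows * row_h_deg * px_per_deg

  n_px <- stim_area_px(px_per_deg)
  img <- matrix(paper, n_px, n_px)
  x0 <- (n_px - word_w_px) / 2
  y0 <- (n_px - word_h_px) / 2
  # Inverse-map each pixel in the word's bounding box to its glyph cell.
  px_x <- which(seq_len(n_px) > x0 & seq_len(n_px) <= x0 + word_w_px)
  px_y <- which(seq_len(n_px) > y0 & seq_len(n_px) <= y0 + word_h_px)
  cell_col <- pmin(grid_cols, pmax(1L, ceiling((px_x - 0.5 - x0) / (col_w_deg * px_per_deg))))
  cell_row <- pmin(grid_rows, pmax(1L, ceiling((px_y - 0.5 - y0) / (row_h_deg * px_per_deg))))
  img[px_y, px_x][grid[cell_row, cell_col]] <- ink
  luminance_image(img, px_per_deg = px_per_deg)
}

#' Generate a synthetic word bank
#'
#' Produces `n` distinct pronounceable-looking 5-letter strings
#' (consonant/vowel alternations) for simulations; a synthetic stand-in for
#' the word lists used with human observers, which are not redistributed.
#'
#' @param n Number of words.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct 5-letter words.
#' @export
make_word_bank <- function(n, seed = 1) {
  cons <- strsplit("bcdfghjklmnprstvz", "")[[1]]
  vows <- strsplit("aeiou", "")[[1]]
  out <- character(0)
  k <- 0L
  with_seed_(derive_seed(seed, 101L), {
    while (length(out) < n && k < 50L) {
      k <- k + 1L
      w <- vapply(seq_len(2L * n), function(i) {
        paste0(
          sample(cons, 1), sample(vows, 1), sample(cons, 1),
          sample(vows, 1), sample(cons, 1)
        )
      }, character(1))
      out <- unique(c(out, w))
    }
  })
  if (length(out) < n) abort("could not generate enough distinct words")
  out[seq_len(n)]
}
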