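#' Render a binary letter stimulus
#'
#' Draws one of the four letters H, T, S, C as a binary raster on a
#' visual-field grid.  Each glyph is built from simple geometric strokes
#' filling an axis-aligned square guide box centred on fixation:
#' * `H` - two vertical bars joined by a central crossbar,
#' * `T` - a top bar with a central vertical bar,
#' * `C` - an annulus with a wedge-shaped opening facing right,
#' * `S` - two stacked, opposed annulus arcs.
#'
#' `T` has the coarsest spatial layout and `S` the finest, matching the
#' relative reconstruction difficulty expected for such shapes.
#'
#' @param letter One of `"H"`, `"T"`, `"S"`, `"C"`.
#' @param grid A [vf_grid()].
#' @param stroke_width Stroke width in degrees.
#' @param box Side length of the square guide box in degrees.
#' @return A `vf_letter`: the binary raster matrix with attributes
#'   `letter`, `grid`, `stroke_width` and `box`.
#' @examples
#' img <- render_letter("T", vf_grid(60, 60))
#' sum(img)  # number of on-pixels
#' @export
render_letter <- function(letter, grid = vf_grid(), stroke_width = 1.2, box = 8) {
  stopifnot(inherits(grid, "vf_grid"))
  if (!is.character(letter) || length(letter) != 1 || !letter %in% c("H", "T", "S", "C")) {
    stop(sprintf("unknown letter id: '%s' (must be one of H, T, S, C)", letter),
         call. = FALSE)
  }
  if (!is.numeric(stroke_width) || stroke_width <= 0 || stroke_width >= box) {
    stop(sprintf("stroke_width must lie in (0, %g), got %g", box, stroke_width),
         call. = FALSE)
  }
  px <- pixel_centers(grid)
  on <- letter_mask(letter, px$x, px$y, stroke_width, box)
  img <- devectorize_image(as.numeric(on), grid)
  structure(img, letter = letter, grid = grid,
            stroke_width = stroke_width, box = box,
            class = c("vf_letter", "matrix", "array"))
}

# Point-in-glyph predicate, vectorized over pixel centres.
letter_mask <- function(letter, x, y, sw, box) {
  hb <- box / 2
  in_bar <- function(x0, x1, y0, y1) x >= x0 & x <= x1 & y >= y0 & y <= y1
  in_annulus <- function(cx, cy, r_in, r_out, keep_angle) {
    dx <- x - cx
    dy <- y - cy
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    r >= r_in & r <= r_out & keep_angle(th)
  }
  switch(letter,
    H = in_bar(-hb, -hb + sw, -hb, hb) |
        in_bar(hb - sw, hb, -hb, hb) |
        in_bar(-hb + sw, hb - sw, -sw / 2, sw / 2),
    T = in_bar(-hb, hb, hb - sw, hb) |
        in_bar(-sw / 2, sw / 2, -hb, hb - sw),
    # C: annulus filling the box, opening within +/- 45 degrees of the +x axis
    C = in_annulus(0, 0, hb - sw, hb,
                   function(th) abs(th) > pi / 4),
    # S: top arc open at the lower right, bottom arc open at the upper left
    S = {
      r_mid <- hb / 2 - sw / 2
      top <- in_annulus(0, hb / 2, r_mid - sw / 2, r_mid + sw / 2,
                        function(th) !(th > -pi / 2 & th < 0))
      bottom <- in_annulus(0, -hb / 2, r_mid - sw / 2, r_mid + sw / 2,
                           function(th) !(th > pi / 2 & th < pi))
      top | bottom
    }
  )
}

#' Render all four letters
#'
#' @inheritParams render_letter
#' @return A named list of `vf_letter` rasters for H, T, S, C.
#' @export
letter_set <- function(grid = vf_grid(), stroke_width = 1.2, box = 8) {
  ltrs <- c("H", "T", "S", "C")
  stats::setNames(
    lapply(ltrs, render_letter, grid = grid, stroke_width = stroke_width, box = box),
    ltrs
  )
}

#' Bar-aperture mapping sequence
#'
#' Generates the retinotopic-mapping stimulus: a bar aperture swept across
#' the visual field in discrete steps at four orientations.  For each
#' orientation the bar traverses the full projected extent of the raster
#' (so that every pixel is covered), with the order of the steps
#' randomized independently within each orientation x repetition block.
#' One frame is shown per volume.
#'
#' @param grid A [vf_grid()].
#' @param seed Integer seed for the step-order randomization.
#' @param bar_width Bar width in degrees.
#' @param n_steps Steps per traversal.
#' @param orientations Bar orientations in degrees (bar is perpendicular
#'   to its direction of motion).
#' @param repetitions Traversals per orientation.
#' @return A `vf_apertures` object: a `p x n_frames` matrix of binary
#'   frames (pixels in row-major vector order, one column per volume)
#'   with a `sequence` tibble attribute recording
#'   `(frame, orientation, repetition, step, center)`.
#' @examples
#' ap <- render_bar_apertures(vf_grid(40, 40), seed = 1)
#' ncol(ap)  # 288 frames
#' @export
render_bar_apertures <- function(grid = vf_grid(), seed = 1, bar_width = 1.33,
                                 n_steps = 12, orientations = c(0, 45, 90, 135),
                                 repetitions = 6) {
  stopifnot(inherits(grid, "vf_grid"), bar_width > 0, n_steps >= 2, repetitions >= 1)
  px <- pixel_centers(grid)
  p <- nrow(px)

  # Unique step frames per orientation: band of pixels whose coordinate
  # projected on the motion axis falls within bar_width/2 of the step centre.
  frames_for <- function(theta_deg) {
    th <- theta_deg * pi / 180
    # motion axis is perpendicular to the bar orientation
    proj <- px$x * cos(th + pi / 2) + px$y * sin(th + pi / 2)
    span <- range(proj)
    spacing <- diff(span) / n_steps
    centers <- span[1] + spacing * (seq_len(n_steps) - 0.5)
    f <- vapply(centers,
                function(ctr) as.numeric(abs(proj - ctr) <= bar_width / 2),
                numeric(p))
    list(frames = f, centers = centers)
  }
  base <- lapply(orientations, frames_for)

  frames <- matrix(0, p, 0)
  seq_meta <- list()
  with_seed(seed, {
    for (rep_i in seq_len(repetitions)) {
      for (oi in seq_along(orientations)) {
        ord <- sample.int(n_steps)
        frames <- cbind(frames, base[[oi]]$frames[, ord, drop = FALSE])
        seq_meta[[length(seq_meta) + 1]] <- tibble::tibble(
          orientation = orientations[oi],
          repetition = rep_i,
          step = ord,
          center = base[[oi]]$centers[ord]
        )
      }
    }
  })
  seq_tbl <- dplyr::bind_rows(seq_meta)
  seq_tbl$frame <- seq_len(nrow(seq_tbl))
  seq_tbl <- seq_tbl[, c("frame", "orientation", "repetition", "step", "center")]
  structure(frames, grid = grid, sequence = seq_tbl,
            bar_width = bar_width, seed = as.integer(seed),
            class = c("vf_apertures", "matrix", "array"))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run `expr` under a local, reproducible RNG stream without disturbing the
# caller's RNG state. `seed = NULL` leaves the global stream in use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed. Keeps values
# in the positive 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587
  as.integer(h + 1)
}
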