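#' Triangular membership function
#'
#' Builds a triangular membership function with vertices `left <= apex <= right`.
#' Membership is 0 outside `[left, right]`, 1 at the apex and piecewise linear
#' in between. End terms of a linguistic variable are *shoulder-clamped*: with
#' `shoulder = "left"` membership stays 1 for all `x <= apex` (and symmetrically
#' for `"right"`), which keeps the universe fully covered at its boundaries.
#'
#' @param label Linguistic term, one of [fuzzy_terms()].
#' @param left,apex,right Vertex abscissae in universe units.
#' @param shoulder `"none"` (default), `"left"` or `"right"`.
#' @return An object of class `tri_mf`.
#' @seealso [membership()], [linguistic_variable()]
#' @export
#' @examples
#' mf <- triangular_mf("ZR", -1, 0, 1)
#' membership(c(-2, -0.5, 0, 0.5, 2), mf)
triangular_mf <- function(label, left, apex, right, shoulder = c("none", "left", "right")) {
  shoulder <- match.arg(shoulder)
  if (!is.numeric(left) || !is.numeric(apex) || !is.numeric(right) ||
      left > apex || apex > right) {
    abort("malformed membership function: need left <= apex <= right",
          class = "precool_config_error")
  }
  structure(list(label = label, left = left, apex = apex, right = right,
                 shoulder = shoulder),
            class = "tri_mf")
}

#' Membership degree of crisp values
#'
#' Fuzzification primitive: converts crisp values into grades of membership
#' for one triangular term. Values outside the support return 0; shoulder
#' terms return 1 beyond their apex toward the clamped side.
#'
#' @param x Numeric vector of crisp values (may lie outside the support).
#' @param mf A [triangular_mf()].
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
membership <- function(x, mf) {
  if (!inherits(mf, "tri_mf")) abort("`mf` must be a tri_mf", class = "precool_config_error")
  up <- if (mf$shoulder == "left" || mf$apex == mf$left) {
    rep(1, length(x))
  } else {
    (x - mf$left) / (mf$apex - mf$left)
  }
  dn <- if (mf$shoulder == "right" || mf$apex == mf$right) {
    rep(1, length(x))
  } else {
    (mf$right - x) / (mf$right - mf$apex)
  }
  deg <- ifelse(x <= mf$apex, up, dn)
  lo_ok <- if (mf$shoulder == "left") TRUE else x >= mf$left
  hi_ok <- if (mf$shoulder == "right") TRUE else x <= mf$right
  out <- ifelse(lo_ok & hi_ok, deg, 0)
  pmin(pmax(out, 0), 1)
}

#' Linguistic variable with seven triangular terms
#'
#' Lays seven triangular membership functions (NL ... PL) over the universe
#' `[lo, hi]`. Apexes are placed evenly *per side of zero* -- NL, NM, NS evenly
#' from `lo` to 0 and PS, PM, PL evenly from 0 to `hi`, with ZR at 0 -- so the
#' zero term peaks at zero even on an asymmetric universe. Each term's feet sit
#' at its neighbours' apexes (50 % overlap) and the two end terms are
#' shoulder-clamped, which guarantees complete coverage: every point of the
#' universe has positive total membership. On a symmetric universe this layout
#' coincides with plain even spacing.
#'
#' @param name Variable name, e.g. `"error"`, `"change_of_error"`,
#'   `"speed_variation"`.
#' @param lo,hi Universe of discourse bounds, `lo < 0 < hi`.
#' @return An object of class `lvar`: list with `name`, `lo`, `hi` and `mfs`
#'   (named list of seven [triangular_mf()]).
#' @export
#' @examples
#' err <- linguistic_variable("error", -1, 1)
#' membership(0.25, err$mfs$PS)
linguistic_variable <- function(name, lo, hi) {
  if (!(lo < 0 && 0 < hi)) {
    abort("universe must straddle zero (lo < 0 < hi)", class = "precool_config_error")
  }
  apex <- c(seq(lo, 0, length.out = 4L)[1:3], seq(0, hi, length.out = 4L))
  mfs <- lapply(1:7, function(i) {
    left  <- if (i == 1L) apex[1L] else apex[i - 1L]
    right <- if (i == 7L) apex[7L] else apex[i + 1L]
    shoulder <- if (i == 1L) "left" else if (i == 7L) "right" else "none"
    triangular_mf(fuzzy_terms()[i], left, apex[i], right, shoulder)
  })
  names(mfs) <- fuzzy_terms()
  structure(list(name = name, lo = lo, hi = hi, mfs = mfs), class = "lvar")
}

#' Membership degrees for all seven terms
#'
#' @param x Numeric vector.
#' @param var An [linguistic_variable()].
#' @return A numeric matrix, `length(x)` rows by 7 columns (NL ... PL).
#' @export
membership_matrix <- function(x, var) {
  m <- vapply(var$mfs, function(mf) membership(x, mf), numeric(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, fuzzy_terms()))
  m
}

#' @export
print.lvar <- function(x, ...) {
  cat(sprintf("<linguistic variable '%s' on [%g, %g]>\n", x$name, x$lo, x$hi))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a linguistic variable into a vertex table
#'
#' @param x An [linguistic_variable()].
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `left`, `apex`, `right`,
#'   `shoulder`.
#' @export
tidy.lvar <- function(x, ...) {
  purrr::map(x$mfs, ~ tibble(term = .x$label, left = .x$left, apex = .x$apex,
                             right = .x$right, shoulder = .x$shoulder)) |>
    dplyr::bind_rows()
}

clip_to <- function(x, lo, hi) pmin(pmax(x, lo), hi)
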