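# Two-level orthogonal screening designs.
#
# The shipped catalogue covers L4(2^3), L8(2^7) and L12(2^11). L4 and L8 are
# the classical fractional-factorial arrays; L12 is the 12-run
# Plackett-Burman design, built from its cyclic generator row, in which
# two-factor interactions are partially confounded across *all* columns --
# the price paid for screening up to 11 factors in 12 runs.

.oa_l4 <- function() {
  matrix(c(1, 1, 1,
           1, 2, 2,
           2, 1, 2,
           2, 2, 1), nrow = 4, byrow = TRUE)
}

.oa_l8 <- function() {
  matrix(c(1, 1, 1, 1, 1, 1, 1,
           1, 1, 1, 2, 2, 2, 2,
           1, 2, 2, 1, 1, 2, 2,
           1, 2, 2, 2, 2, 1, 1,
           2, 1, 2, 1, 2, 1, 2,
           2, 1, 2, 2, 1, 2, 1,
           2, 2, 1, 1, 2, 2, 1,
           2, 2, 1, 2, 1, 1, 2), nrow = 8, byrow = TRUE)
}

# Plackett-Burman N = 12: cyclic shifts of the generator row (+ mapped to
# level 2, - to level 1) followed by the all-minus run.
.oa_l12 <- function() {
  gen <- c(2L, 2L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 2L, 1L)
  k <- length(gen)
  rows <- vapply(0:(k - 1), function(s) gen[((seq_len(k) - 1 - s) %% k) + 1],
                 integer(k))
  rbind(t(rows), rep(1L, k))
}

.oa_catalogue <- function() {
  list(L4 = .oa_l4(), L8 = .oa_l8(), L12 = .oa_l12())
}

#' Generate a two-level orthogonal array
#'
#' Returns the smallest catalogued design (`L4`, `L8`, `L12`) with at least
#' `n_factors` columns. Every column is balanced (equal runs at each level)
#' and every pair of columns is orthogonal (each of the four level
#' combinations occurs `n_runs/4` times).
#'
#' @param n_factors Number of two-level factors to accommodate (1--11).
#' @return An object of class `taguchi_oa`: a list with `name`, `n_runs`,
#'   `n_columns` and the `n_runs x n_columns` level matrix `cells`
#'   (entries 1 or 2).
#' @examples
#' oa_array(10)           # the 12-run Plackett-Burman array
#' as_tibble(oa_array(3)) # L4 run sheet
#' @export
oa_array <- function(n_factors) {
  if (!is.numeric(n_factors) || length(n_factors) != 1 ||
      is.na(n_factors) || n_factors < 1 || n_factors != round(n_factors)) {
    abort_input("`n_factors` must be a single positive integer.")
  }
  cat <- .oa_catalogue()
  sizes <- vapply(cat, ncol, integer(1))
  ok <- which(sizes >= n_factors)
  if (length(ok) == 0) {
    abort(
      sprintf(
        "%d factors exceed the largest catalogued design (L12, 11 columns).",
        n_factors),
      class = "lfaquant_error_design")
  }
  name <- names(cat)[ok[1]]
  cells <- cat[[name]]
  storage.mode(cells) <- "integer"
  structure(
    list(name = name, n_runs = nrow(cells), n_columns = ncol(cells),
         cells = cells),
    class = "taguchi_oa")
}

#' @export
print.taguchi_oa <- function(x, ...) {
  cat(sprintf("<%s orthogonal array: %d runs x %d two-level columns>\n",
              x$name, x$n_runs, x$n_columns))
  print(x$cells)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.taguchi_oa <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$cells),
                           .name_repair = ~ sprintf("col%d", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(run = seq_len(x$n_runs)), out)
}

#' Verify balance and pairwise orthogonality of a design
#'
#' Checks, exhaustively, that every column holds each level in exactly half
#' the runs and that every pair of distinct columns shows each of the four
#' level combinations in exactly `n_runs/4` runs.
#'
#' @param design A `taguchi_oa` object.
#' @return `TRUE` (invisibly) if the design passes; otherwise an error
#'   describing the first violated property.
#' @export
check_orthogonality <- function(design) {
  stopifnot(inherits(design, "taguchi_oa"))
  m <- design$cells
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j] == 1L) != n / 2) {
      abort(sprintf("column %d is unbalanced", j),
            class = "lfaquant_error_design")
    }
  }
  for (a in seq_len(ncol(m) - 1)) {
    for (b in (a + 1):ncol(m)) {
      counts <- table(factor(m[, a], 1:2), factor(m[, b], 1:2))
      if (any(counts != n / 4)) {
        abort(sprintf("columns %d and %d are not orthogonal", a, b),
              class = "lfaquant_error_design")
      }
    }
  }
  invisible(TRUE)
}
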