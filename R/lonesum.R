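#' Lonesum test for a binary connectivity matrix
#'
#' A binary matrix is *lonesum* when no 2 x 2 sub-block (any row pair by any
#' column pair) equals (1 0 / 0 1) or (0 1 / 1 0); equivalently it can be
#' permuted into a descending staircase of 1's, and equivalently its row
#' supports are totally ordered by inclusion.  Lonesum matrices are exactly
#' the configurations the threshold-1 ratchet network can reach, and are
#' counted by the poly-Bernoulli numbers.
#'
#' @param A binary integer matrix.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_lonesum(matrix(c(1, 0, 0, 1), 2, 2))   # FALSE: forbidden pattern
#' is_lonesum(matrix(c(1, 0, 1, 1), 2, 2))   # TRUE
is_lonesum <- function(A) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("is_lonesum expects a binary matrix")
  n <- nrow(A)
  if (n < 2 || ncol(A) < 2) return(TRUE)
  # nested row supports <=> no forbidden 2x2 pattern (binary case)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- A[i, ] > 0; rj <- A[j, ] > 0
    if (any(ri & !rj) && any(!ri & rj)) return(FALSE)
  }
  TRUE
}

#' Constructive word for a lonesum configuration
#'
#' Builds a word that, applied to the all-zero configuration of the
#' `(n, m, 1, 1)` threshold-1 ratchet network, produces exactly the given
#' lonesum matrix.  Rows are processed from narrowest to widest; each group
#' of rows with equal width contributes its K's followed by P's on the
#' columns beyond that width.  Later, wider rows never disturb earlier,
#' narrower ones, which is the inductive heart of the staircase argument.
#'
#' @param A binary lonesum matrix.
#' @return A word (token vector); empty for the zero matrix.
#' @export
#' @examples
#' A <- matrix(c(0, 0, 1, 1), 2, 2)   # rows 01 / 01
#' w <- staircase_word(A)
#' sp <- ratchet_spec(nrow(A), ncol(A))
#' connectivity_matrix(apply_word(zero_config(sp), w, sp), sp)  # == A
staircase_word <- function(A) {
  A <- as.matrix(A)
  if (!is_lonesum(A)) stop("matrix is not lonesum; no generating word exists at T = 1")
  m <- ncol(A)
  widths <- rowSums(A > 0)
  nz <- which(widths > 0)
  if (length(nz) == 0) return(character(0))
  # ascending width; ties broken by ascending row index (any staircase
  # permutation is acceptable -- replay is the contract)
  ord <- nz[order(widths[nz], nz)]
  w <- character(0)
  done_width <- -1L
  for (grp in split(ord, widths[ord])) {
    wd <- widths[grp[1]]
    w <- c(w, paste0("K", grp))
    if (wd < m) {
      # clear the columns this group leaves OFF
      offcols <- which(A[grp[1], ] == 0)
      w <- c(w, paste0("P", offcols))
    }
    done_width <- wd
  }
  w
}

#' Constructive word for an arbitrary binary pattern at threshold 2
#'
#' At threshold `T = 2` every binary ON/OFF pattern of the `l = 1` ratchet
#' network is reachable: states can pass through 1 from above and below, so
#' the lonesum restriction dissolves.  This builds the inductive word: rows
#' are staged bottom-up in a 1-2 configuration (2 at ON positions, 1 at OFF
#' positions), each new row's P-sweep temporarily lowers the finished rows,
#' which are then re-raised; a final P-sweep produces the 0-1 pattern and a
#' final K-sweep lifts it so that ON targets sit at threshold.
#'
#' @param pattern binary `n x m` matrix of desired ON (state 2) positions.
#' @return A word replaying from zero to a configuration whose state-2 set
#'   equals `pattern`.
#' @export
#' @examples
#' sp <- ratchet_spec(2, 2, T = 2)
#' patt <- matrix(c(1, 0, 0, 1), 2, 2)   # forbidden at T = 1
#' x <- apply_word(zero_config(sp), t2_constructive_word(patt), sp)
#' all((connectivity_matrix(x, sp) == 2) == (patt == 1))
t2_constructive_word <- function(pattern) {
  pattern <- as.matrix(pattern)
  if (!all(pattern %in% c(0, 1))) stop("pattern must be binary")
  n <- nrow(pattern); m <- ncol(pattern)
  w <- character(0)
  for (k in n:1) {
    on <- which(pattern[k, ] == 1)
    off <- setdiff(seq_len(m), on)
    # lower the finished rows on the ON columns, double-pump row k, then
    # lower everything on the OFF columns and re-raise the finished rows
    w <- c(w,
           paste0("P", on, recycle0 = TRUE),
           paste0("K", c(k, k)),
           paste0("P", off, recycle0 = TRUE),
           if (k < n) paste0("K", n:(k + 1)))
  }
  c(w, paste0("P", seq_len(m)), paste0("K", seq_len(n)))
}
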