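#' Alphabet after deleting a regulator
#'
#' Removes one regulator's action from the alphabet; the target set and the
#' network's connectivity are unchanged, so the impaired network explores a
#' subset of the full network's configurations.
#'
#' @param spec a [ratchet_spec()] or [seq_spec()].
#' @param action token of the regulator to delete (e.g. `"K1"`).
#' @return Character vector of remaining action tokens.
#' @export
#' @examples
#' delete_regulator(ratchet_spec(3, 2), "K1")
delete_regulator <- function(spec, action) {
  a <- parse_action(action)   # validates the token
  ab <- full_alphabet(spec)
  tok <- paste0(a$kind, a$index)
  if (!(tok %in% ab)) stop("unknown regulator: ", tok)
  setdiff(ab, tok)
}

#' Correlation between two ON/OFF configurations
#'
#' Pearson correlation (default) or cosine similarity of two equal-length
#' binary target vectors.  Zero-variance vectors make Pearson undefined;
#' the convention here is 1 for identical vectors and 0 otherwise (cosine:
#' all-zero vs anything nonzero scores 0).
#'
#' @param a,b binary vectors of equal length.
#' @param method `"pearson"` or `"cosine"`.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' config_correlation(c(1, 1, 0, 0), c(0, 0, 1, 1))   # -1
#' config_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0))   # 0
config_correlation <- function(a, b, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("length mismatch")
  if (method == "cosine") {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(if (identical(as.numeric(a), as.numeric(b))) 1 else 0)
    return(sum(a * b) / (na * nb))
  }
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(if (identical(as.numeric(a), as.numeric(b))) 1 else 0)
  stats::cor(a, b)
}

#' Regulator-deletion recovery analysis
#'
#' The robustness experiment: enumerate the reachable sets of the full
#' network and of the network with one regulator deleted, drop every full
#' configuration the impaired network matches exactly, and ask how close the
#' impaired network can get to each lost configuration.  Rows of the
#' correlation matrix are the lost configurations, columns the impaired
#' ones; per-row maxima summarise recoverability and their empirical CDF
#' (with `1 - F(cutoff)` as the recovered fraction) quantifies it.
#'
#' @param spec a threshold-1 [ratchet_spec()].
#' @param deleted action token of the deleted regulator (default `"K1"`).
#' @param cutoff similarity cutoff (default 0.8).
#' @param min_extra_len optional: keep only impaired configurations whose
#'   shortest word is longer than in the full network by at least this many
#'   actions (mirrors the "longer sequences" construction); `NULL` (the
#'   default, documented prominently) keeps the impaired set length-agnostic.
#' @param method correlation method, see [config_correlation()].
#' @param max_states capacity cap for the BFS.
#' @return An object of class `robustness_result`: list with `full`,
#'   `impaired` (reachable sets), `lost` (row indices into the full set),
#'   `corr` (matrix, lost x impaired), `row_max`, `cdf` (a step function;
#'   `NULL` when nothing is lost), `fraction_above` (`NA` when nothing is
#'   lost), `reach_count` and the parameters.
#' @export
#' @examples
#' rr <- recovery_analysis(ratchet_spec(3, 2))
#' rr$reach_count
#' rr$fraction_above
recovery_analysis <- function(spec, deleted = "K1", cutoff = 0.8,
                              min_extra_len = NULL,
                              method = c("pearson", "cosine"),
                              max_states = 1e7) {
  stopifnot(inherits(spec, "ratchet_spec"))
  if (spec$T != 1) stop("the recovery analysis is defined at threshold T = 1")
  method <- match.arg(method)
  full <- bfs_reachable(spec, max_states = max_states)
  impaired <- bfs_reachable(spec, alphabet = delete_regulator(spec, deleted),
                            max_states = max_states)
  imp_keep <- seq_len(nrow(impaired$configs))
  if (!is.null(min_extra_len)) {
    full_depth <- full$depth[match(impaired$keys, full$keys)]
    imp_keep <- which(impaired$depth >= full_depth + min_extra_len)
  }
  imp_configs <- impaired$configs[imp_keep, , drop = FALSE]
  imp_keys <- impaired$keys[imp_keep]

  lost <- which(!(full$keys %in% imp_keys))
  corr <- matrix(numeric(0), 0, length(imp_keys))
  row_max <- numeric(0)
  if (length(lost) > 0 && length(imp_keys) > 0) {
    corr <- matrix(0, length(lost), length(imp_keys))
    for (r in seq_along(lost)) {
      a <- full$configs[lost[r], ]
      corr[r, ] <- vapply(seq_len(nrow(imp_configs)), function(cc)
        config_correlation(a, imp_configs[cc, ], method), numeric(1))
    }
    row_max <- apply(corr, 1, max)
  }
  cdf <- if (length(row_max)) stats::ecdf(row_max) else NULL
  fraction_above <- if (length(row_max)) mean(row_max > cutoff) else NA_real_
  structure(list(
    spec = spec, deleted = deleted, cutoff = cutoff, method = method,
    full = full, impaired = impaired, lost = lost,
    corr = corr, row_max = row_max, cdf = cdf,
    fraction_above = fraction_above,
    reach_count = nrow(full$configs)
  ), class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "robustness: (n=%d, m=%d, l_n=%d) minus %s | reach %d, impaired %d, lost %d, frac > %.2f: %s\n",
    x$spec$n, x$spec$m, x$spec$l_n, x$deleted,
    x$reach_count, nrow(x$impaired$configs), length(x$lost), x$cutoff,
    format(x$fraction_above, digits = 3)))
  invisible(x)
}

#' Reachability / robustness tradeoff table
#'
#' Scans `(n, l_n)` at fixed `m`, deleting one regulator, and tabulates the
#' number of reachable configurations against the recovered fraction above
#' the similarity cutoff.  Increasing connectivity trades reachability for
#' recoverability.
#'
#' @param m number of P's (fixed).
#' @param n_range,l_n_range integer vectors to scan (cells with
#'   `l_n > n` are skipped).
#' @param cutoff similarity cutoff.
#' @param deleted deleted regulator token.
#' @param ... passed to [recovery_analysis()].
#' @return Data frame with columns `n`, `l_n`, `reach_count`,
#'   `fraction_above`.
#' @export
tradeoff_curve <- function(m, n_range, l_n_range, cutoff = 0.8,
                           deleted = "K1", ...) {
  rows <- list()
  for (n in n_range) for (l_n in l_n_range) {
    if (l_n > n) next
    rr <- recovery_analysis(ratchet_spec(n, m, l_n, 1, 1),
                            deleted = deleted, cutoff = cutoff, ...)
    rows[[length(rows) + 1]] <- data.frame(
      n = n, l_n = l_n,
      reach_count = rr$reach_count,
      fraction_above = rr$fraction_above)
  }
  do.call(rbind, rows)
}
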