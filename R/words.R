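#' Parse a word of regulator actions
#'
#' A *word* is a finite ordered sequence of actions over the alphabet
#' `{K_1..K_n, P_1..P_m}`, written as whitespace-separated tokens such as
#' `"K1 K2 P1"`.  Words apply left-to-right: the first-listed action acts
#' first.  Distinct orderings of the same multiset of actions may produce
#' distinct configurations (noncommutativity).
#'
#' @param text a single string of whitespace-separated tokens, or a
#'   character vector of tokens.  The empty string is the identity word.
#' @return A character vector of validated tokens (possibly length 0).
#' @export
#' @examples
#' parse_word("K1 K2 P1")
#' parse_word("")           # identity
parse_word <- function(text) {
  if (length(text) == 0) return(character(0))
  if (length(text) == 1 && !grepl("^[KP]", text[1])) {
    # allow "" and pure-whitespace as the empty word
    if (!nzchar(trimws(text[1]))) return(character(0))
  }
  toks <- if (length(text) == 1) strsplit(trimws(text), "\\s+")[[1]] else text
  toks <- toks[nzchar(toks)]
  ok <- grepl("^[KP][0-9]+$", toks)
  if (any(!ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("bad action token '%s' at position %d (expected e.g. K1, P2)",
                 toks[bad], bad))
  }
  idx <- as.integer(sub("^[KP]", "", toks))
  if (any(idx < 1)) {
    bad <- which(idx < 1)[1]
    stop(sprintf("bad action token '%s' at position %d (indices are 1-based)",
                 toks[bad], bad))
  }
  toks
}

# split a token into kind ("K"/"P") and 1-based index
parse_action <- function(token) {
  token <- parse_word(token)
  if (length(token) != 1) stop("expected a single action token")
  list(kind = substr(token, 1, 1), index = as.integer(substring(token, 2)))
}

#' Format a word as a single string
#' @param word character vector of action tokens.
#' @return A single string, `""` for the empty word.
#' @export
format_word <- function(word) paste(word, collapse = " ")

#' Apply a word of actions to a configuration
#'
#' Left-to-right fold of the single-action update of the model family the
#' spec belongs to ([ratchet_apply()] or [seq_apply()]).
#'
#' @param config integer state vector.
#' @param word a word (string or token vector, see [parse_word()]).
#' @param spec a [ratchet_spec()] or [seq_spec()].
#' @param trajectory if `TRUE`, return the matrix of intermediate
#'   configurations (one row per step, including the start) instead of just
#'   the final configuration.
#' @return The final configuration, or the trajectory matrix.
#' @export
#' @examples
#' sp <- ratchet_spec(2, 2)
#' connectivity_matrix(apply_word(zero_config(sp), "K1 K2 P1", sp), sp)
apply_word <- function(config, word, spec, trajectory = FALSE) {
  toks <- parse_word(word)
  if (trajectory) {
    out <- matrix(0L, length(toks) + 1L, length(config))
    out[1, ] <- config
    for (s in seq_along(toks)) {
      a <- parse_action(toks[s])
      config <- apply_action(spec, config, a$kind, a$index)
      out[s + 1L, ] <- config
    }
    rownames(out) <- c("start", toks)
    return(out)
  }
  for (tok in toks) {
    a <- parse_action(tok)
    config <- apply_action(spec, config, a$kind, a$index)
  }
  config
}

#' Full action alphabet of a network
#'
#' @param spec a [ratchet_spec()] or [seq_spec()].
#' @return Character vector of action tokens, K's first.
#' @export
full_alphabet <- function(spec) {
  if (inherits(spec, "ratchet_spec"))
    c(paste0("K", seq_len(spec$n)), paste0("P", seq_len(spec$m)))
  else
    c(paste0("K", seq_len(spec$n)), paste0("P", seq_len(spec$n)))
}
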