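#' Read a network specification from JSON
#'
#' Schema: `{"model": "ratchet" | "sequestration" | "combinatorial", ...}`
#' with fields `n`, `m`, `l_n`, `l_m`, `T` for ratchet (defaults
#' `l_n = l_m = T = 1`), `n`, `reduced` for sequestration (default
#' `reduced = true`), and `n_i`, `l_ni` for combinatorial pools.
#'
#' @param path path to a JSON file.
#' @return A [ratchet_spec()], [seq_spec()] or [comb_spec()].
#' @export
read_spec <- function(path) {
  js <- jsonlite::fromJSON(path)
  if (is.null(js$model))
    stop("spec file ", path, ": missing required field 'model'")
  switch(as.character(js$model),
    ratchet = {
      for (f in c("n", "m")) if (is.null(js[[f]]))
        stop("ratchet spec: missing required field '", f, "'")
      ratchet_spec(js$n, js$m,
                   l_n = if (is.null(js$l_n)) 1 else js$l_n,
                   l_m = if (is.null(js$l_m)) 1 else js$l_m,
                   T = if (is.null(js$T)) 1 else js$T)
    },
    sequestration = {
      if (is.null(js$n)) stop("sequestration spec: missing required field 'n'")
      seq_spec(js$n, reduced = if (is.null(js$reduced)) TRUE else js$reduced)
    },
    combinatorial = {
      if (is.null(js$n_i)) stop("combinatorial spec: missing required field 'n_i'")
      comb_spec(js$n_i, l_ni = if (is.null(js$l_ni)) 1 else js$l_ni)
    },
    stop("unknown model '", js$model, "' in ", path)
  )
}

#' Write a network specification to JSON
#'
#' Round-trips with [read_spec()].
#'
#' @param spec a [ratchet_spec()], [seq_spec()] or [comb_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  js <- if (inherits(spec, "ratchet_spec")) {
    list(model = "ratchet", n = spec$n, m = spec$m,
         l_n = spec$l_n, l_m = spec$l_m, T = spec$T)
  } else if (inherits(spec, "seq_spec")) {
    list(model = "sequestration", n = spec$n, reduced = spec$reduced)
  } else if (inherits(spec, "comb_spec")) {
    list(model = "combinatorial", n_i = spec$n_i, l_ni = spec$l_ni)
  } else stop("unsupported spec")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Seeded fixture generator
#'
#' Generates reproducible random network specs and word suites for
#' property-style testing: identical seeds give identical fixtures.
#'
#' @param family `"ratchet"` or `"sequestration"`.
#' @param n_specs number of spec/word-suite pairs.
#' @param seed RNG seed.
#' @param max_n,max_m upper bounds for regulator counts.
#' @param max_T upper bound for the ratchet threshold.
#' @param words_per_spec words generated per spec.
#' @param max_len maximum word length (uniform on `0..max_len`, so identity
#'   words are included).
#' @return A list of fixtures; each has `spec` and `words` (a character
#'   vector of word strings).
#' @export
#' @examples
#' fx <- fixture_generator("ratchet", 2, seed = 7)
#' identical(fx, fixture_generator("ratchet", 2, seed = 7))
fixture_generator <- function(family = c("ratchet", "sequestration"),
                              n_specs = 5, seed = 1,
                              max_n = 4, max_m = 4, max_T = 2,
                              words_per_spec = 10, max_len = 12) {
  family <- match.arg(family)
  set.seed(seed)
  out <- vector("list", n_specs)
  for (s in seq_len(n_specs)) {
    if (family == "ratchet") {
      n <- sample.int(max_n, 1); m <- sample.int(max_m, 1)
      spec <- ratchet_spec(n, m,
                           l_n = sample.int(n, 1), l_m = sample.int(m, 1),
                           T = sample.int(max_T, 1))
    } else {
      n <- max(2L, sample.int(max_n, 1))
      spec <- seq_spec(n, reduced = sample(c(TRUE, FALSE), 1))
    }
    ab <- full_alphabet(spec)
    words <- vapply(seq_len(words_per_spec), function(i) {
      len <- sample.int(max_len + 1, 1) - 1L
      if (len == 0) "" else paste(sample(ab, len, replace = TRUE), collapse = " ")
    }, character(1))
    out[[s]] <- list(spec = spec, words = words)
  }
  out
}

#' Write a reachable set as CSV
#'
#' One row per configuration: the canonical target states plus the witness
#' word (when recorded).  A comment header embeds the spec parameters so
#' the run can be reproduced.
#'
#' @param rs a `reachable_set` from [bfs_reachable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reachable_csv <- function(rs, path) {
  sp <- rs$spec
  hdr <- if (inherits(sp, "ratchet_spec"))
    sprintf("# model=ratchet n=%d m=%d l_n=%d l_m=%d T=%d alphabet=%s",
            sp$n, sp$m, sp$l_n, sp$l_m, sp$T, paste(rs$alphabet, collapse = "+"))
  else
    sprintf("# model=sequestration n=%d reduced=%s alphabet=%s",
            sp$n, sp$reduced, paste(rs$alphabet, collapse = "+"))
  df <- as.data.frame(rs$configs)
  names(df) <- paste0("t", seq_len(ncol(df)))
  if (!is.null(rs$words)) df$word <- rs$words
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
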