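# Plain-text serialization of a model library: a format-version line, a
# small header, then one block per model. Probabilities are printed with
# %.17g so doubles round-trip losslessly.

LIBRARY_FORMAT <- "substrateHMM-library 1"

#' Write / read a model library
#'
#' The format is line-oriented plain text: a format-version line (a version
#' mismatch on read is a hard error), header lines (`domain_type`, `mode`,
#' `threshold_bits`, `models`), then one block per model carrying the name,
#' substrate, subgroup index, match-state count, background frequencies,
#' emission rows and transition rows at full double precision. The
#' write/read pair is a lossless round trip.
#'
#' @param library A `substrate_hmm` library (non-empty, unique model names).
#' @param path Output path.
#' @export
write_model_library <- function(library, path) {
  stopifnot(inherits(library, "substrate_hmm"))
  if (!length(library$models)) stopf("refusing to write an empty library")
  if (anyDuplicated(names(library$models))) {
    stopf("duplicate model name: '%s'",
          names(library$models)[duplicated(names(library$models))][1L])
  }
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("%s", LIBRARY_FORMAT)
  w("domain_type %s", library$domain_type)
  w("mode %s", library$mode)
  w("threshold_bits %s", num17(library$threshold_bits))
  w("models %d", length(library$models))
  for (m in library$models) {
    w("model %s", m$name)
    w("substrate %s", m$substrate)
    w("subgroup %d", m$subgroup)
    w("match_states %d", m$M)
    w("n_train %d", m$n_train)
    w("alphabet %s", paste(m$alphabet, collapse = ""))
    w("background %s", num_row(m$background))
    w("members %s", paste(library$groups[[m$name]], collapse = " "))
    w("match_emissions")
    for (k in seq_len(m$M)) w("%s", num_row(m$match_emissions[k, ]))
    w("insert_emissions")
    for (k in seq_len(m$M + 1L)) w("%s", num_row(m$insert_emissions[k, ]))
    w("transitions %s", paste(colnames(m$transitions), collapse = " "))
    for (k in seq_len(m$M + 1L)) w("%s", num_row(m$transitions[k, ]))
    w("end model")
  }
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)
num_row <- function(x) paste(num17(x), collapse = " ")

#' @rdname write_model_library
#' @return `read_model_library()` returns the `substrate_hmm` library.
#' @export
read_model_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != LIBRARY_FORMAT) {
    stopf("unsupported library format (expected '%s', got '%s')",
          LIBRARY_FORMAT, if (length(lines)) lines[1L] else "<empty>")
  }
  pos <- 2L
  take <- function(key) {
    line <- lines[pos]
    pos <<- pos + 1L
    if (!startsWith(line, paste0(key, " ")) && line != key) {
      stopf("library parse error at line %d: expected '%s'", pos - 1L, key)
    }
    sub(paste0("^", key, " ?"), "", line)
  }
  domain_type <- take("domain_type")
  mode <- take("mode")
  threshold_bits <- as.numeric(take("threshold_bits"))
  n_models <- as.integer(take("models"))
  models <- list()
  groups <- list()
  bg <- NULL
  for (i in seq_len(n_models)) {
    name <- take("model")
    substrate <- take("substrate")
    subgroup <- as.integer(take("subgroup"))
    M <- as.integer(take("match_states"))
    n_train <- as.integer(take("n_train"))
    alphabet <- chars(take("alphabet"))
    background <- stats::setNames(scan_row(take("background")), alphabet)
    member_str <- take("members")
    members <- if (nzchar(member_str)) strsplit(member_str, " ")[[1L]] else character(0)
    take("match_emissions")
    match_em <- read_block(lines, pos, M); pos <- pos + M
    take("insert_emissions")
    insert_em <- read_block(lines, pos, M + 1L); pos <- pos + M + 1L
    tr_cols <- strsplit(take("transitions"), " ")[[1L]]
    trans <- read_block(lines, pos, M + 1L); pos <- pos + M + 1L
    colnames(trans) <- tr_cols
    take("end model")
    colnames(match_em) <- alphabet
    colnames(insert_em) <- alphabet
    models[[name]] <- structure(
      list(name = name, substrate = substrate, subgroup = subgroup, M = M,
           alphabet = alphabet, background = background,
           match_emissions = match_em, insert_emissions = insert_em,
           transitions = trans, n_train = n_train),
      class = "profile_hmm")
    groups[[name]] <- members
    bg <- background
  }
  structure(
    list(domain_type = domain_type, mode = mode, models = models,
         groups = groups, threshold_bits = threshold_bits,
         excluded = data.frame(substrate = character(0), n = integer(0)),
         pseudocount = NA_real_, background = bg),
    class = "substrate_hmm")
}

scan_row <- function(line) as.numeric(strsplit(line, " ")[[1L]])

read_block <- function(lines, pos, n) {
  do.call(rbind, lapply(seq_len(n), function(k) scan_row(lines[pos + k - 1L])))
}
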