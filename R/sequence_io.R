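#' Sanitize a raw protein sequence
#'
#' Uppercases and strips whitespace, then applies the non-standard-residue
#' policy. The 13 descriptor property tables cover exactly the 20 canonical
#' residues, so ambiguity codes (B, J, O, U, X, Z) and stop marks (`*`)
#' cannot be encoded: under `"strict"` (the default) any such character is
#' an error; under `"drop-unknown"` they are removed and their count is
#' attached as the `"n_dropped"` attribute.
#'
#' @param raw Character scalar, the raw sequence.
#' @param policy `"strict"` or `"drop-unknown"`.
#' @param id Optional record id used in error messages.
#' @return Sanitized residue string over the 20-letter alphabet, with
#'   attribute `n_dropped` (0 under strict).
#' @export
#' @examples
#' sanitize_sequence("acd ef")
#' sanitize_sequence("ACXDF", policy = "drop-unknown")
sanitize_sequence <- function(raw, policy = c("strict", "drop-unknown"),
                              id = NULL) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", toupper(raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- chars %in% aa_alphabet()
  label <- if (is.null(id)) "sequence" else paste0("sequence '", id, "'")
  if (policy == "strict") {
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(label, ": non-standard residue '", chars[bad], "' at position ", bad,
           " (use policy = \"drop-unknown\" to remove such residues)",
           call. = FALSE)
    }
    n_dropped <- 0L
  } else {
    n_dropped <- sum(!ok)
    chars <- chars[ok]
  }
  if (length(chars) == 0L) {
    stop(label, ": empty after removing non-standard residues", call. = FALSE)
  }
  structure(paste(chars, collapse = ""), n_dropped = n_dropped)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file and sanitizes
#' each record with [sanitize_sequence()]. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @param policy Non-standard residue policy, see [sanitize_sequence()].
#' @return Named character vector of residue strings; names are record ids,
#'   unique within the file.
#' @export
read_fasta <- function(path, policy = c("strict", "drop-unknown")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records",
                              call. = FALSE)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in '", path, "'",
                              call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  raw <- as.character(set)
  out <- vapply(seq_along(raw), function(i) {
    as.character(sanitize_sequence(raw[i], policy = policy, id = ids[i]))
  }, character(1))
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be a named character vector", call. = FALSE)
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a labeled protein-pair table
#'
#' Reads a delimited text file with three columns: id of protein A, id of
#' protein B, and a binary interaction label (1 = interacting,
#' 0 = non-interacting). Tab- and comma-delimited files are autodetected; a
#' header row is detected by a non-binary third field. Row order is
#' preserved.
#'
#' @param path Path to the pair table.
#' @param sequences Named character vector of residue strings (e.g. from
#'   [read_fasta()]) against which every pair id must resolve. `NULL` skips
#'   the resolution check.
#' @return A data frame with columns `id_a`, `id_b` (character) and
#'   `label` (integer 0/1).
#' @export
read_pair_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("pair table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pair table '", path, "' is empty", call. = FALSE)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    stop("pair table '", path, "': line ", bad[1], " does not have 3 ",
         if (sep == "\t") "tab" else "comma", "-separated fields", call. = FALSE)
  }
  m <- matrix(trimws(unlist(fields)), ncol = 3, byrow = TRUE)
  if (!m[1, 3] %in% c("0", "1")) m <- m[-1, , drop = FALSE]  # header row
  if (nrow(m) == 0L) stop("pair table '", path, "' has no data rows", call. = FALSE)
  if (!all(m[, 3] %in% c("0", "1"))) {
    bad <- which(!m[, 3] %in% c("0", "1"))[1]
    stop("pair table '", path, "': malformed label '", m[bad, 3],
         "' (expected 0 or 1)", call. = FALSE)
  }
  pairs <- data.frame(id_a = m[, 1], id_b = m[, 2],
                      label = as.integer(m[, 3]),
                      stringsAsFactors = FALSE)
  if (!is.null(sequences)) {
    unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(sequences))
    if (length(unknown) > 0L) {
      stop("pair table '", path, "' references unknown protein id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  pairs
}

#' Write a labeled protein-pair table
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path; tab-separated, no header.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
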