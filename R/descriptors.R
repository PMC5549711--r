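#' Amino-acid frequency descriptor
#'
#' Fraction of each of the 20 canonical residues in the sequence, in
#' alphabetical residue order. Entries sum to 1.
#'
#' @param residues Residue string.
#' @return Named numeric vector of length 20 (`freq.A` .. `freq.Y`).
#' @export
#' @examples
#' frequency_descriptor("ACAC")
frequency_descriptor <- function(residues) {
  chars <- .residue_chars(residues)
  counts <- table(factor(chars, levels = aa_alphabet()))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("freq.", aa_alphabet())
  out
}

#' CTD composition descriptor
#'
#' Fraction of sequence positions falling in each of the three groups of a
#' qualitative property encoding. Entries sum to 1.
#'
#' @param groups Integer vector of group indices in 1..3 (from
#'   [encode_qualitative()]).
#' @return Numeric vector of length 3.
#' @export
ctd_composition <- function(groups) {
  .check_groups(groups)
  tabulate(groups, nbins = 3L) / length(groups)
}

#' CTD transition descriptor
#'
#' For each unordered group pair (1,2), (1,3), (2,3), the percentage of
#' adjacent residue positions whose groups form that pair in either order:
#' `100 * count / (n - 1)`.
#'
#' @param groups Integer vector of group indices in 1..3, length >= 2.
#' @return Numeric vector of length 3, values in \[0, 100\].
#' @export
ctd_transition <- function(groups) {
  .check_groups(groups)
  n <- length(groups)
  if (n < 2L) stop("transition needs a sequence of length >= 2", call. = FALSE)
  a <- groups[-n]
  b <- groups[-1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  counts <- c(sum(lo == 1L & hi == 2L),
              sum(lo == 1L & hi == 3L),
              sum(lo == 2L & hi == 3L))
  100 * counts / (n - 1)
}

#' CTD distribution descriptor
#'
#' For each group k = 1..3, the percent chain positions at which the first,
#' 25%, 50%, 75% and 100% of that group's residues are reached. The q-th
#' entry is `100 * p / n` where p is the 1-based position of the
#' `ceiling(q * m)`-th occurrence of the group (m = number of occurrences;
#' "first" is occurrence 1, "100%" is occurrence m). A group absent from
#' the sequence contributes five zeros.
#'
#' @param groups Integer vector of group indices in 1..3.
#' @return Numeric vector of length 15 (five values for group 1, then group
#'   2, then group 3), values in \[0, 100\].
#' @export
ctd_distribution <- function(groups) {
  .check_groups(groups)
  n <- length(groups)
  qs <- c(0, 0.25, 0.50, 0.75, 1)   # 0 stands for "first occurrence"
  out <- numeric(15)
  for (k in 1:3) {
    pos <- which(groups == k)
    m <- length(pos)
    if (m == 0L) next
    idx <- pmax(1L, ceiling(qs * m))
    out[(k - 1L) * 5L + 1:5] <- 100 * pos[idx] / n
  }
  out
}

.check_groups <- function(groups) {
  if (length(groups) == 0L) stop("empty group sequence", call. = FALSE)
  if (!all(groups %in% 1:3)) stop("group indices must be in 1..3", call. = FALSE)
  invisible(groups)
}

#' Auto-covariance descriptor
#'
#' Lag-indexed covariance of a numerically encoded sequence with itself:
#' \deqn{AC(lag) = \frac{1}{n-lag} \sum_{i=1}^{n-lag}
#'       (v_i - \bar v)(v_{i+lag} - \bar v)}
#' where \eqn{\bar v} is the mean over all n positions. Captures the
#' interaction between residues `lag` positions apart. The encoded values
#' are mean-centered within the sequence, so AC is invariant under adding a
#' constant to every position.
#'
#' @param values Numeric vector (from [encode_quantitative()]).
#' @param max_lag Largest lag; requires `length(values) > max_lag`.
#' @return Numeric vector of length `max_lag` (lags 1..max_lag).
#' @export
auto_covariance <- function(values, max_lag = 30L) {
  n <- length(values)
  if (max_lag < 1L) stop("max_lag must be >= 1", call. = FALSE)
  if (n <= max_lag) {
    stop("auto-covariance with max_lag = ", max_lag, " needs a sequence of ",
         "length at least ", max_lag + 1L, " (got ", n, ")", call. = FALSE)
  }
  centered <- values - mean(values)
  vapply(seq_len(max_lag), function(lag) {
    sum(centered[seq_len(n - lag)] * centered[seq_len(n - lag) + lag]) / (n - lag)
  }, numeric(1))
}

#' Descriptor vector column names
#'
#' The fixed layout of the per-protein descriptor vector: the 20 frequency
#' entries, then per qualitative property its composition (3), transition
#' (3) and distribution (15) blocks, then per quantitative scale its
#' auto-covariance block (lags 1..max_lag).
#'
#' @param tables Property tables, see [aa_property_tables()].
#' @param max_lag Auto-covariance maximum lag.
#' @return Character vector of descriptor names, e.g. `d.charge.g2.p50`,
#'   `ac.H.lag7`.
#' @export
feature_names <- function(tables = aa_property_tables(), max_lag = 30L) {
  freq <- paste0("freq.", aa_alphabet())
  ctd <- unlist(lapply(names(tables$qualitative), function(p) {
    c(paste0("c.", p, ".g", 1:3),
      paste0("t.", p, ".", c("g12", "g13", "g23")),
      paste0("d.", p, ".g", rep(1:3, each = 5), ".",
             rep(c("first", "p25", "p50", "p75", "p100"), 3)))
  }))
  ac <- unlist(lapply(names(tables$quantitative), function(p) {
    paste0("ac.", p, ".lag", seq_len(max_lag))
  }))
  c(freq, ctd, ac)
}

#' Full descriptor vector of one protein
#'
#' Assembles the multi-scale descriptor vector of a protein sequence:
#' frequency (20), composition/transition/distribution over the seven
#' qualitative partitions (7 x 21 = 147), and auto-covariance over the six
#' normalized quantitative scales (6 x max_lag, 180 at the default
#' `max_lag = 30`), for 347 dimensions in total. The frequency + CTD part
#' is the qualitative-characteristic (QLC) block; the auto-covariance part
#' is the quantitative-characteristic (QNC) block.
#'
#' @param residues Residue string; length must exceed `max_lag`.
#' @param tables Property tables, see [aa_property_tables()].
#' @param max_lag Auto-covariance maximum lag (default 30).
#' @return Named numeric vector of length `20 + 147 + 6 * max_lag`.
#' @export
#' @examples
#' v <- protein_features(paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = ""))
#' length(v)
protein_features <- function(residues, tables = aa_property_tables(),
                             max_lag = 30L) {
  chars <- .residue_chars(residues)
  n <- length(chars)
  if (n <= max_lag) {
    stop("descriptor extraction needs sequences longer than max_lag = ",
         max_lag, " residues (got ", n, ")", call. = FALSE)
  }
  freq <- frequency_descriptor(residues)
  ctd <- unlist(lapply(tables$qualitative, function(prop) {
    g <- encode_qualitative(residues, prop)
    c(ctd_composition(g), ctd_transition(g), ctd_distribution(g))
  }), use.names = FALSE)
  ac <- unlist(lapply(tables$quantitative, function(scale) {
    v <- encode_quantitative(residues, normalize_property_scale(scale))
    auto_covariance(v, max_lag = max_lag)
  }), use.names = FALSE)
  out <- c(unname(freq), ctd, ac)
  names(out) <- feature_names(tables, max_lag)
  out
}

#' Pair descriptor vector
#'
#' Concatenates the descriptor vectors of the two proteins of a pair, in
#' the (A, B) order of the pair record, giving a 694-dimensional vector at
#' the default settings.
#'
#' @param fa,fb Descriptor vectors of proteins A and B (equal length).
#' @return Numeric vector of length `2 * length(fa)`, names prefixed
#'   `a.`/`b.`.
#' @export
pair_features <- function(fa, fb) {
  if (length(fa) != length(fb)) {
    stop("pair members have descriptor vectors of different lengths (",
         length(fa), " vs ", length(fb), ")", call. = FALSE)
  }
  out <- c(unname(fa), unname(fb))
  names(out) <- c(paste0("a.", names(fa)), paste0("b.", names(fb)))
  out
}

#' Descriptor matrix for a set of proteins
#'
#' @param sequences Named character vector of residue strings.
#' @param tables Property tables.
#' @param max_lag Auto-covariance maximum lag.
#' @return Numeric matrix, one row per protein (rownames = ids), one column
#'   per descriptor.
#' @export
protein_feature_matrix <- function(sequences, tables = aa_property_tables(),
                                   max_lag = 30L) {
  if (is.null(names(sequences))) stop("sequences must be named", call. = FALSE)
  rows <- lapply(sequences, protein_features, tables = tables, max_lag = max_lag)
  m <- do.call(rbind, rows)
  rownames(m) <- names(sequences)
  m
}

#' Pair descriptor matrix for a labeled pair set
#'
#' Computes per-protein descriptors once and assembles the concatenated
#' pair vectors for every row of a pair table.
#'
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally
#'   `label`.
#' @param sequences Named character vector of residue strings covering
#'   every id in `pairs`.
#' @param tables Property tables.
#' @param max_lag Auto-covariance maximum lag.
#' @param augment_symmetric If `TRUE`, append the swapped (B, A) ordering of
#'   every pair as an extra row (labels duplicated), enforcing order
#'   symmetry at training time. Off by default.
#' @return List with `x` (numeric matrix of pair vectors) and `y` (integer
#'   labels, or `NULL` when `pairs` has no label column).
#' @export
pair_feature_matrix <- function(pairs, sequences,
                                tables = aa_property_tables(), max_lag = 30L,
                                augment_symmetric = FALSE) {
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing_ids <- setdiff(ids, names(sequences))
  if (length(missing_ids) > 0L) {
    stop("no sequence for protein id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  pf <- protein_feature_matrix(sequences[ids], tables = tables, max_lag = max_lag)
  x <- cbind(pf[pairs$id_a, , drop = FALSE], pf[pairs$id_b, , drop = FALSE])
  colnames(x) <- c(paste0("a.", colnames(pf)), paste0("b.", colnames(pf)))
  rownames(x) <- NULL
  y <- if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL
  if (augment_symmetric) {
    xs <- cbind(pf[pairs$id_b, , drop = FALSE], pf[pairs$id_a, , drop = FALSE])
    colnames(xs) <- colnames(x)
    rownames(xs) <- NULL
    x <- rbind(x, xs)
    if (!is.null(y)) y <- c(y, y)
  }
  list(x = x, y = y)
}

#' Write / read a descriptor matrix as headered CSV
#'
#' One row per protein or pair; first column `id` (rownames), remaining
#' columns the named descriptor values.
#'
#' @param x Descriptor matrix with rownames and colnames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_csv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
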