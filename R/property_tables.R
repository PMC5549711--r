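#' The 20-letter amino-acid alphabet
#'
#' Canonical one-letter codes in alphabetical order. This order fixes the
#' layout of the frequency block of the protein descriptor vector.
#'
#' @return Character vector of the 20 canonical residues.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Seven qualitative properties: each partitions the 20 residues into three
# groups. Group semantics per property (e.g. charge: 1 = positive,
# 2 = neutral, 3 = negative).
#
# The secondary-structure strand group is commonly mis-printed in the
# literature as {V,I,T,C,W,F,T} (T twice, Y missing, 19 residues covered);
# the registry uses the standard CTD grouping {V,I,Y,C,W,F,T}, restoring a
# complete partition. See the methods vignette.
.qualitative_groups <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),                 # polar
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),            # neutral
    g3 = c("C", "L", "V", "I", "M", "F", "W")             # hydrophobic
  ),
  vdw_volume = list(                                      # normalized van der Waals volume
    g1 = c("G", "A", "S", "T", "P", "D"),
    g2 = c("N", "V", "E", "C", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")
  ),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")
  ),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")
  ),
  charge = list(
    g1 = c("K", "R"),                                     # positive
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L",
           "M", "F", "P", "S", "T", "W", "Y", "V"),       # neutral
    g3 = c("D", "E")                                      # negative
  ),
  secondary_structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),       # helix
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),            # strand (amended, see above)
    g3 = c("G", "N", "P", "S", "D")                       # coil
  ),
  solvent_accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),       # buried
    g2 = c("R", "K", "Q", "E", "N", "D"),                 # exposed
    g3 = c("M", "S", "P", "T", "H", "Y")                  # intermediate
  )
)

# Six quantitative per-residue scales, ordered A..Y as in aa_alphabet():
#   H     hydrophobicity
#   VSC   volume of the side chain (A^3)
#   P1    polarity
#   P2    polarizability
#   SASA  solvent-accessible surface area
#   NCISC net charge index of the side chain
.quantitative_scales <- local({
  tab <- matrix(c(
    # H      VSC     P1    P2     SASA   NCISC
    0.62,   27.5,   8.1,  0.046, 1.181,  0.007187,   # A
    0.29,   44.6,   5.5,  0.128, 1.461, -0.03661,    # C
    -0.90,  40.0,  13.0,  0.105, 1.587, -0.02382,    # D
    -0.74,  62.0,  12.3,  0.151, 1.862, -0.006802,   # E
    1.19,  115.5,   5.2,  0.290, 2.228,  0.037552,   # F
    0.48,    0.0,   9.0,  0.000, 0.881,  0.179052,   # G
    -0.40,  79.0,  10.4,  0.230, 2.025, -0.01069,    # H
    1.38,   93.5,   5.2,  0.186, 1.810,  0.021631,   # I
    -1.50, 100.0,  11.3,  0.219, 2.258,  0.017708,   # K
    1.06,   93.5,   4.9,  0.186, 1.931,  0.051672,   # L
    0.64,   94.1,   5.7,  0.221, 2.034,  0.002683,   # M
    -0.78,  58.7,  11.6,  0.134, 1.655,  0.005392,   # N
    0.12,   41.9,   8.0,  0.131, 1.468,  0.239531,   # P
    -0.85,  80.7,  10.5,  0.180, 1.932,  0.049211,   # Q
    -2.53, 105.0,  10.5,  0.291, 2.560,  0.043587,   # R
    -0.18,  29.3,   9.2,  0.062, 1.298,  0.004627,   # S
    -0.05,  51.3,   8.6,  0.108, 1.525,  0.003352,   # T
    1.08,   71.5,   5.9,  0.140, 1.645,  0.057004,   # V
    0.81,  145.5,   5.4,  0.409, 2.663,  0.037977,   # W
    0.26,  117.3,   6.2,  0.298, 2.368,  0.0323599   # Y
  ), nrow = 20, byrow = TRUE)
  rownames(tab) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  colnames(tab) <- c("H", "VSC", "P1", "P2", "SASA", "NCISC")
  lapply(stats::setNames(colnames(tab), colnames(tab)), function(j) tab[, j])
})

#' Built-in physicochemical property tables
#'
#' Returns the descriptor property registry: seven qualitative properties,
#' each a three-group partition of the 20 canonical residues, and six
#' quantitative per-residue scales (hydrophobicity H, side-chain volume VSC,
#' polarity P1, polarizability P2, solvent-accessible surface area SASA and
#' net charge index of the side chain NCISC). Qualitative properties feed
#' the composition/transition/distribution descriptors; quantitative scales
#' feed the auto-covariance descriptor after zero-mean/unit-sd normalization
#' over the 20 residues (see [normalize_property_scale()]).
#'
#' @param overrides Optional path to a plain key-value override file. Each
#'   non-comment line is `name: value`, where for a qualitative property the
#'   value is three residue-set strings separated by `/` (e.g.
#'   `charge: KR/ANCQGHILMFPSTWYV/DE`), and for a quantitative scale it is 20
#'   numbers in alphabetical residue order, whitespace-separated. Only
#'   listed properties are replaced.
#' @return An object of class `aa_property_tables`: a list with elements
#'   `qualitative` (named list; per property a named integer vector mapping
#'   each residue to its group in 1..3) and `quantitative` (named list of
#'   named numeric vectors of length 20, raw, un-normalized values).
#' @export
#' @examples
#' tabs <- aa_property_tables()
#' tabs$qualitative$charge[c("K", "R", "D", "E")]
#' tabs$quantitative$H[c("A", "R")]
aa_property_tables <- function(overrides = NULL) {
  qual <- lapply(.qualitative_groups, .groups_to_map)
  quant <- .quantitative_scales
  if (!is.null(overrides)) {
    ov <- .read_property_overrides(overrides)
    for (nm in names(ov$qualitative)) qual[[nm]] <- ov$qualitative[[nm]]
    for (nm in names(ov$quantitative)) quant[[nm]] <- ov$quantitative[[nm]]
  }
  out <- list(qualitative = qual, quantitative = quant)
  class(out) <- "aa_property_tables"
  validate_property_tables(out)
  out
}

# residue -> group index map from a list of three residue-character groups
.groups_to_map <- function(groups) {
  map <- integer(0)
  for (k in 1:3) {
    g <- groups[[k]]
    map[g] <- k
  }
  map <- map[aa_alphabet()]
  names(map) <- aa_alphabet()
  map
}

#' Validate a property table set
#'
#' Checks that every qualitative property is a complete, disjoint partition
#' of the 20 canonical residues into groups 1..3, and that every
#' quantitative scale provides exactly one finite value per residue with
#' non-zero spread.
#'
#' @param tables An `aa_property_tables` object (or a bare list with the
#'   same structure, e.g. from a user-supplied override).
#' @return `tables`, invisibly. Errors describe the offending property.
#' @export
validate_property_tables <- function(tables) {
  ab <- aa_alphabet()
  for (nm in names(tables$qualitative)) {
    map <- tables$qualitative[[nm]]
    if (!setequal(names(map), ab) || anyNA(map[ab])) {
      stop("qualitative property '", nm, "' does not cover all 20 residues",
           call. = FALSE)
    }
    if (!all(map %in% 1:3)) {
      stop("qualitative property '", nm, "' has group indices outside 1..3",
           call. = FALSE)
    }
  }
  for (nm in names(tables$quantitative)) {
    v <- tables$quantitative[[nm]]
    if (!setequal(names(v), ab) || anyNA(v[ab]) || !all(is.finite(v[ab]))) {
      stop("quantitative scale '", nm, "' must give one finite value per residue",
           call. = FALSE)
    }
    if (stats::sd(v) == 0) {
      stop("quantitative scale '", nm, "' is constant (zero standard deviation)",
           call. = FALSE)
    }
  }
  invisible(tables)
}

#' Normalize a quantitative residue scale
#'
#' Centers and scales a 20-value residue scale to zero mean and unit
#' standard deviation over the 20 canonical residues:
#' \eqn{P'_{i,j} = (P_{i,j} - \bar{P_j}) / S_j}. The constants are computed
#' over the amino-acid alphabet, not over the residues of any particular
#' sequence; per-sequence centering happens separately inside the
#' auto-covariance descriptor.
#'
#' The population (divide-by-n) standard deviation is used, so that the 20
#' normalized values themselves have unit population sd.
#'
#' @param values Named numeric vector of length 20 (names = residues).
#' @return Named numeric vector of normalized values, alphabetical order.
#' @export
#' @examples
#' h <- aa_property_tables()$quantitative$H
#' round(mean(normalize_property_scale(h)), 12)
normalize_property_scale <- function(values) {
  if (length(values) != 20L || is.null(names(values))) {
    stop("a quantitative scale must be a named vector of 20 residue values",
         call. = FALSE)
  }
  values <- values[aa_alphabet()]
  if (anyNA(values)) stop("scale is missing values for some residues", call. = FALSE)
  mu <- mean(values)
  sdev <- sqrt(mean((values - mu)^2))
  if (sdev == 0) stop("cannot normalize a constant scale (zero standard deviation)",
                      call. = FALSE)
  (values - mu) / sdev
}

# Parse the plain key-value override format described in aa_property_tables().
.read_property_overrides <- function(path) {
  if (!file.exists(path)) stop("override file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(qualitative = list(), quantitative = list())
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed override line: ", ln, call. = FALSE)
    nm <- trimws(parts[1])
    val <- trimws(parts[2])
    if (grepl("/", val, fixed = TRUE)) {
      sets <- strsplit(val, "/", fixed = TRUE)[[1]]
      if (length(sets) != 3L) {
        stop("qualitative override '", nm, "' needs three '/'-separated groups",
             call. = FALSE)
      }
      groups <- lapply(sets, function(s) {
        strsplit(gsub("[ ,]", "", toupper(s)), "")[[1]]
      })
      out$qualitative[[nm]] <- .groups_to_map(groups)
    } else {
      num <- as.numeric(strsplit(val, "[[:space:],]+")[[1]])
      if (length(num) != 20L || anyNA(num)) {
        stop("quantitative override '", nm,
             "' needs 20 numeric values in alphabetical residue order",
             call. = FALSE)
      }
      names(num) <- aa_alphabet()
      out$quantitative[[nm]] <- num
    }
  }
  out
}

#' @export
print.aa_property_tables <- function(x, ...) {
  cat("Amino-acid property tables\n")
  cat("  qualitative partitions: ", paste(names(x$qualitative), collapse = ", "), "\n")
  cat("  quantitative scales:    ", paste(names(x$quantitative), collapse = ", "), "\n")
  invisible(x)
}
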