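#' Configuration for the synthetic PPI benchmark generator
#'
#' The generator emulates a curated golden-positive / golden-negative PPI
#' benchmark with a planted physicochemical signal. Every protein is
#' assigned a latent class, hydrophobic-biased or polar-biased; residues are
#' drawn i.i.d. from a 20-letter distribution in which the hydrophobic
#' group (C, L, V, I, M, F, W — group 3 of the hydrophobicity partition)
#' has its probability multiplied by `exp(effect)` (hydrophobic-biased) or
#' `exp(-effect)` (polar-biased) before renormalization. `effect = 0` gives
#' uniform residue usage and hence no recoverable signal.
#'
#' @param n_proteins Number of proteins in the proteome (split evenly
#'   between the two latent classes). The default provides one protein per
#'   pair at the default pair counts, keeping protein reuse across pairs
#'   low; heavy reuse lets a flexible classifier shortcut the task by
#'   memorizing individual proteins instead of reading the planted
#'   physicochemical signal.
#' @param length_range Integer (min, max) sequence length; min must exceed
#'   the descriptor maximum lag (>= 31 at the default lag 30).
#' @param n_pos,n_neg Number of positive / negative pairs.
#' @param effect Signal strength, >= 0 (log-scale reweighting of the
#'   hydrophobic residue group).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 400L, length_range = c(50L, 200L),
                         n_pos = 200L, n_neg = 200L, effect = 0, seed = 1L) {
  if (n_proteins < 4L) stop("need at least 4 proteins", call. = FALSE)
  if (length(length_range) != 2L || length_range[1] > length_range[2]) {
    stop("length_range must be (min, max) with min <= max", call. = FALSE)
  }
  if (length_range[1] < 31L) {
    stop("minimum sequence length must be >= 31 so descriptors are defined",
         call. = FALSE)
  }
  if (n_pos < 0L || n_neg < 0L || n_pos + n_neg < 1L) {
    stop("need at least one pair", call. = FALSE)
  }
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect = as.numeric(effect), seed = as.integer(seed)),
            class = "synth_config")
}

# residue sampling distribution of one latent class
.class_residue_probs <- function(effect, class) {
  hydrophobic <- c("C", "L", "V", "I", "M", "F", "W")
  w <- rep(1, 20)
  names(w) <- aa_alphabet()
  sign <- if (class == "hydrophobic") 1 else -1
  w[hydrophobic] <- w[hydrophobic] * exp(sign * effect)
  w / sum(w)
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` sequences under the latent-class residue
#' distributions of the configuration (see [synth_config()]). The first
#' half of the proteome is hydrophobic-biased, the second half
#' polar-biased.
#'
#' @param cfg A `synth_config` object.
#' @return Named character vector of residue strings (ids `prot0001`, ...)
#'   with attribute `latent_class` (character vector, same order).
#' @export
generate_proteins <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_hydro <- cfg$n_proteins %/% 2L
  classes <- rep(c("hydrophobic", "polar"),
                 c(n_hydro, cfg$n_proteins - n_hydro))
  probs <- list(hydrophobic = .class_residue_probs(cfg$effect, "hydrophobic"),
                polar = .class_residue_probs(cfg$effect, "polar"))
  seqs <- .with_seed(cfg$seed, {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    vapply(seq_len(cfg$n_proteins), function(i) {
      paste(sample(aa_alphabet(), lens[i], replace = TRUE,
                   prob = probs[[classes[i]]]), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("prot%04d", seq_len(cfg$n_proteins))
  attr(seqs, "latent_class") <- classes
  seqs
}

#' Generate a labeled synthetic PPI dataset
#'
#' Builds the proteome with [generate_proteins()] and samples labeled
#' pairs: positive pairs join two proteins of the SAME latent class,
#' negative pairs join proteins of OPPOSITE classes, so at `effect > 0` the
#' interaction label is recoverable from the physicochemical descriptors
#' while at `effect = 0` the labels carry no signal.
#'
#' @param cfg A `synth_config` object.
#' @return List with `sequences` (named character vector) and `pairs`
#'   (data frame `id_a`, `id_b`, `label` with `n_pos` positives followed by
#'   `n_neg` negatives).
#' @export
#' @examples
#' ds <- generate_ppi_dataset(synth_config(n_proteins = 10, n_pos = 5,
#'                                         n_neg = 5, effect = 2))
#' table(ds$pairs$label)
generate_ppi_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sequences <- generate_proteins(cfg)
  classes <- attr(sequences, "latent_class")
  ids <- names(sequences)
  by_class <- split(ids, classes)
  if (any(lengths(by_class) < 2L) || length(by_class) < 2L) {
    stop("too few proteins per latent class to build pairs", call. = FALSE)
  }
  pairs <- .with_seed(cfg$seed + 1L, {
    pos <- t(vapply(seq_len(cfg$n_pos), function(i) {
      cls <- sample(names(by_class), 1L)
      sample(by_class[[cls]], 2L)
    }, character(2)))
    neg <- t(vapply(seq_len(cfg$n_neg), function(i) {
      # shuffle so the slot order never encodes the latent class
      sample(c(sample(by_class[[1]], 1L), sample(by_class[[2]], 1L)))
    }, character(2)))
    data.frame(
      id_a = c(if (cfg$n_pos > 0) pos[, 1], if (cfg$n_neg > 0) neg[, 1]),
      id_b = c(if (cfg$n_pos > 0) pos[, 2], if (cfg$n_neg > 0) neg[, 2]),
      label = rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg)),
      stringsAsFactors = FALSE
    )
  })
  list(sequences = sequences, pairs = pairs)
}
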