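#' Configure a synthetic sgRNA dataset
#'
#' Describes a generator for labeled target contexts: flank and spacer bases
#' are uniform-random, the PAM GG is planted at the layout positions, and the
#' efficiency label is drawn `Bernoulli(plogis(intercept + sum coef * feature
#' + N(0, noise_sd)))`. Planted effects reference the same feature
#' definitions the extractors compute, so generative truth and measured
#' features are exactly commensurable.
#'
#' Effect descriptors are lists with fields:
#' * `type = "freq_mono"`, `value = "T"`: spacer mononucleotide frequency;
#' * `type = "freq_dinuc"`, `value = "TT"`: overlapping spacer dinucleotide
#'   frequency (denominator L - 1);
#' * `type = "pd_dinuc"`, `pos`, `value`: indicator of dinucleotide `value`
#'   starting at context position `pos`;
#' and a `coef` field in every case.
#'
#' @param n number of records (>= 2).
#' @param seed RNG seed.
#' @param spacer_len 20 or 19.
#' @param window 40 or 30.
#' @param effects list of effect descriptors (see Details).
#' @param intercept intercept of the label model (tunes class balance).
#' @param gene_count genes assigned round-robin (for leave-one-gene-out).
#' @param noise_sd sd of Gaussian noise added to the linear predictor.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 1000L, seed = 1L, spacer_len = 20L, window = 40L,
                         effects = list(), intercept = 0, gene_count = 10L,
                         noise_sd = 0) {
  stopifnot(n >= 2, gene_count >= 1, noise_sd >= 0)
  locate_spacer(window, spacer_len)   # errors on impossible layouts
  for (e in effects) {
    stopifnot(is.list(e), e$type %in% c("freq_mono", "freq_dinuc", "pd_dinuc"),
              is.numeric(e$coef))
    if (e$type == "pd_dinuc") stopifnot(!is.null(e$pos))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 spacer_len = as.integer(spacer_len), window = as.integer(window),
                 effects = effects, intercept = intercept,
                 gene_count = as.integer(gene_count), noise_sd = noise_sd),
            class = "synth_config")
}

#' Preset synthetic-signal configurations
#'
#' `"tt-negative"` plants a strong negative coefficient on spacer TT
#' frequency (the dominant association reported for real screens: T/TT-rich
#' spacers are inefficient). `"pd-dinuc"` plants position-specific
#' dinucleotide effects that are invisible to position-dependent
#' mononucleotide encodings: at each of four spacer positions, AT/TA score
#' `+c` and AA/TT score `-c`, so every base-level margin is exactly zero.
#' `"null"` has no sequence effect at all.
#'
#' @param preset preset name.
#' @param n,seed,... passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_preset <- function(preset = c("tt-negative", "pd-dinuc", "null"),
                         n = 1000L, seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "tt-negative" = list(
      effects = list(list(type = "freq_dinuc", value = "TT", coef = -20)),
      intercept = 20 / 16),   # centers the linear predictor: E[TT freq] = 1/16
    "pd-dinuc" = {
      pos <- c(13L, 17L, 21L, 25L)
      cf <- 1.5
      eff <- unlist(lapply(pos, function(p) list(
        list(type = "pd_dinuc", pos = p, value = "AT", coef = cf),
        list(type = "pd_dinuc", pos = p, value = "TA", coef = cf),
        list(type = "pd_dinuc", pos = p, value = "AA", coef = -cf),
        list(type = "pd_dinuc", pos = p, value = "TT", coef = -cf))),
        recursive = FALSE)
      list(effects = eff, intercept = 0)
    },
    "null" = list(effects = list(), intercept = 0))
  do.call(synth_config, c(list(n = n, seed = seed), args, list(...)))
}

#' Generate a synthetic labeled sgRNA dataset
#'
#' @param config a `synth_config`.
#' @return an `sgrna_dataset` (validating, like any parsed dataset) with the
#'   generative Bernoulli probabilities attached as attribute `true_prob`.
#' @export
generate_sgrna_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n
  W <- config$window
  chars <- matrix(sample(BASES, n * W, replace = TRUE), nrow = n)
  gg <- pam_gg_positions(W)
  chars[, gg] <- "G"
  seqs <- apply(chars, 1, paste, collapse = "")
  coords <- locate_spacer(W, config$spacer_len)
  sp <- substr(seqs, coords["spacer_start"], coords["spacer_end"])
  lp <- rep(config$intercept, n)
  for (e in config$effects) {
    lp <- lp + e$coef * effect_feature(e, seqs, sp, chars)
  }
  if (config$noise_sd > 0) lp <- lp + rnorm(n, 0, config$noise_sd)
  p <- plogis(lp)
  df <- data.frame(
    id = sprintf("sg%05d", seq_len(n)),
    sequence = seqs,
    label = as.integer(runif(n) < p),
    gene = sprintf("gene%03d", (seq_len(n) - 1L) %% config$gene_count + 1L),
    stringsAsFactors = FALSE)
  ds <- sgrna_dataset(df, window = W, spacer_len = config$spacer_len,
                      name = "synthetic")
  attr(ds, "true_prob") <- p
  ds
}

effect_feature <- function(e, seqs, spacers, chars) {
  L <- nchar(spacers[1])
  switch(e$type,
    freq_mono = vapply(strsplit(spacers, ""), function(ch) mean(ch == e$value),
                       numeric(1)),
    freq_dinuc = vapply(strsplit(spacers, ""), function(ch) {
      sum(paste0(ch[-L], ch[-1]) == e$value) / (L - 1)
    }, numeric(1)),
    pd_dinuc = as.numeric(chars[, e$pos] == substr(e$value, 1, 1) &
                          chars[, e$pos + 1L] == substr(e$value, 2, 2)))
}

#' Empirical Bayes-optimal AUC of a synthetic dataset
#'
#' AUC obtained by scoring each record with its true generative probability;
#' no classifier trained on sequence features can systematically beat this on
#' the same data.
#'
#' @param dataset a dataset from [generate_sgrna_data()].
#' @return AUC of `true_prob` against the drawn labels.
#' @export
bayes_auc <- function(dataset) {
  p <- attr(dataset, "true_prob")
  if (is.null(p)) stop("dataset has no true_prob attribute (not synthetic?)")
  auc_score(p, dataset$label)
}
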