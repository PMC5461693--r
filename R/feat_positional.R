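#' Position-dependent mononucleotide composition (PD Mono)
#'
#' Binary indicator of each base at each retained context position. The two
#' fixed PAM GG positions (32-33 in the 40 bp layout) carry no information and
#' are excluded, leaving 38 positions x 4 bases = 152 columns for a 40 bp
#' window.
#'
#' @param dataset an `sgrna_dataset`.
#' @return a `feature_block` with columns named like `pos07_G`.
#' @export
pd_mono <- function(dataset) {
  window <- attr(dataset, "window")
  keep <- setdiff(seq_len(window), pam_gg_positions(window))
  chars <- seq_matrix(dataset$sequence, window)
  cols <- as.vector(t(outer(keep, BASES, function(p, b) sprintf("pos%02d_%s", p, b))))
  vals <- matrix(0L, nrow(dataset), length(cols))
  for (i in seq_along(keep)) {
    p <- keep[i]
    idx <- (i - 1L) * 4L + match(chars[, p], BASES)
    vals[cbind(seq_len(nrow(dataset)), idx)] <- 1L
  }
  feature_block("PDMono", vals, cols, dataset$id)
}

#' Position-dependent dinucleotide composition (PD Dinuc)
#'
#' Binary indicator of each of the 16 dinucleotides at each retained start
#' position. Any window overlapping the fixed PAM GG positions is dropped
#' (starts 31-33 in the 40 bp layout), leaving 36 starts x 16 = 576 columns.
#'
#' @param dataset an `sgrna_dataset`.
#' @return a `feature_block` with columns named like `pos15_TT`.
#' @export
pd_dinuc <- function(dataset) {
  window <- attr(dataset, "window")
  starts <- pd_dinuc_starts(window)
  chars <- seq_matrix(dataset$sequence, window)
  cols <- as.vector(t(outer(starts, DINUCS, function(p, d) sprintf("pos%02d_%s", p, d))))
  vals <- matrix(0L, nrow(dataset), length(cols))
  for (i in seq_along(starts)) {
    s <- starts[i]
    din <- paste0(chars[, s], chars[, s + 1L])
    idx <- (i - 1L) * 16L + match(din, DINUCS)
    vals[cbind(seq_len(nrow(dataset)), idx)] <- 1L
  }
  feature_block("PDDinuc", vals, cols, dataset$id)
}

pd_dinuc_starts <- function(window) {
  gg <- pam_gg_positions(window)
  drop <- (gg[1] - 1L):gg[2]              # any start whose 2-mer touches the GG
  setdiff(seq_len(window - 1L), drop)
}

#' Spacer mono- and dinucleotide frequencies (Freq)
#'
#' Four single-nucleotide frequencies (counts / L) and sixteen overlapping
#' dinucleotide frequencies (counts / (L - 1)) of the spacer; 20 columns.
#'
#' @param dataset an `sgrna_dataset`.
#' @return a `feature_block` with columns `freq_A` ... `freq_TT`.
#' @export
freq_block <- function(dataset) {
  sp <- spacers(dataset)
  L <- nchar(sp[1])
  mono <- t(vapply(sp, function(s) {
    tabulate(match(strsplit(s, "")[[1]], BASES), 4) / L
  }, numeric(4), USE.NAMES = FALSE))
  din <- t(vapply(sp, function(s) {
    ch <- strsplit(s, "")[[1]]
    d <- paste0(ch[-L], ch[-1])
    tabulate(match(d, DINUCS), 16) / (L - 1)
  }, numeric(16), USE.NAMES = FALSE))
  feature_block("Freq", cbind(mono, din),
                paste0("freq_", c(BASES, DINUCS)), dataset$id)
}

# character matrix: one row per sequence, one column per position
seq_matrix <- function(seqs, width) {
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE), ncol = width, byrow = TRUE)
}
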