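# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (enumeration, literal formulas) so they check the
# package's optimized paths from a different direction.

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# a valid 40 bp context around a given 20 nt spacer
make_context <- function(spacer, flank5 = "ACGTACGTAC", pam_n = "T",
                         flank3 = "AACCGGT") {
  stopifnot(nchar(spacer) == 20, nchar(flank5) == 10, nchar(flank3) == 7)
  paste0(flank5, spacer, pam_n, "GG", flank3)
}

tiny_dataset <- function(spacers, labels = NULL, genes = NULL) {
  df <- data.frame(id = sprintf("r%03d", seq_along(spacers)),
                   sequence = vapply(spacers, make_context, character(1),
                                     USE.NAMES = FALSE))
  if (!is.null(labels)) df$label <- labels
  if (!is.null(genes)) df$gene <- genes
  sgrna_dataset(df)
}

## exhaustive global alignment: enumerate all alignments recursively
bf_nw <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (nchar(a) == 0) return(gap * nchar(b))
  if (nchar(b) == 0) return(gap * nchar(a))
  ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  max(bf_nw(ta, tb, match, mismatch, gap) + if (ha == hb) match else mismatch,
      bf_nw(ta, b, match, mismatch, gap) + gap,
      bf_nw(a, tb, match, mismatch, gap) + gap)
}

## exhaustive secondary-structure enumeration for the MEF model
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# all pseudoknot-free pair sets on ch[i..j] (list of 2-col matrices)
bf_structures <- function(ch, i, j, min_h = 3L) {
  if (j - i < min_h + 1L) return(list(matrix(integer(0), ncol = 2)))
  out <- lapply(bf_structures(ch, i + 1L, j, min_h), identity)
  for (k in (i + min_h + 1L):j) {
    if (ch[k] == COMP[[ch[i]]]) {
      inner <- bf_structures(ch, i + 1L, k - 1L, min_h)
      rest <- if (k + 1L <= j) bf_structures(ch, k + 1L, j, min_h) else
        list(matrix(integer(0), ncol = 2))
      for (si in inner) for (sr in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), si, sr)
      }
    }
  }
  out
}

bf_structure_energy <- function(pairs, ch, dG, hairpin_penalty = 3.5) {
  if (nrow(pairs) == 0) return(0)
  e <- 0
  key <- paste(pairs[, 1], pairs[, 2])
  has <- function(i, j) paste(i, j) %in% key
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (has(i + 1L, j - 1L)) e <- e + dG[[paste0(ch[i], ch[i + 1L])]]
    inside <- pairs[, 1] > i & pairs[, 2] < j
    if (!any(inside)) e <- e + hairpin_penalty   # hairpin loop
  }
  e
}

bf_mef <- function(seq, params, hairpin_penalty = 3.5, min_h = 3L) {
  ch <- strsplit(seq, "")[[1]]
  dG <- params$steps[, "dG"]
  structs <- bf_structures(ch, 1L, length(ch), min_h)
  min(0, min(vapply(structs, bf_structure_energy, numeric(1), ch = ch,
                    dG = dG, hairpin_penalty = hairpin_penalty)))
}

## exhaustive stem-loop placement: check complementarity base by base
bf_lsl <- function(seq, min_loop = 3L, max_loop = 10L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best <- 0L
  for (a in 1:max(1, floor((L - min_loop) / 2))) {
    for (i in seq_len(L)) {
      for (g in min_loop:max_loop) {
        j <- i + a + g                       # arm2 start
        if (j + a - 1L > L) next
        ok <- all(vapply(0:(a - 1L), function(t) {
          ch[i + t] == COMP[[ch[j + a - 1L - t]]]
        }, logical(1)))
        if (ok) best <- max(best, a)
      }
    }
  }
  best
}

## paired permutation test for an AUC difference (sign-flip of score pairing)
perm_auc_test <- function(scores_a, scores_b, labels, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- abs(auc_score(scores_a, labels) - auc_score(scores_b, labels))
  n <- length(labels)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    flip <- runif(n) < 0.5
    a <- ifelse(flip, scores_b, scores_a)
    b <- ifelse(flip, scores_a, scores_b)
    if (abs(auc_score(a, labels) - auc_score(b, labels)) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / n_perm
}
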