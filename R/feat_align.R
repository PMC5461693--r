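#' Needleman-Wunsch global alignment score
#'
#' Optimal global pairwise alignment score under per-base match/mismatch
#' scores and a linear gap penalty.
#'
#' @param a,b nonempty sequences.
#' @param match,mismatch per-aligned-base scores.
#' @param gap per-gap-base penalty (should be <= 0).
#' @return optimal alignment score (numeric scalar).
#' @export
#' @examples
#' needleman_wunsch("ACGT", "ACGT")            # 4
#' needleman_wunsch("A", "T")                  # -1: mismatch beats two gaps
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("both sequences must be nonempty")
  .nw_score(a, b, match, mismatch, gap)
}

#' Seed-scaffold alignment feature class (Align)
#'
#' For each seed size `k` from 5 to the spacer length L, the PAM-proximal
#' k-suffix of the spacer (the seed) is globally aligned against the scaffold
#' sequence and the optimal score is recorded; L - 4 columns (16 for a 20 nt
#' spacer), named `align_k05 ... align_k20`.
#'
#' @param dataset an `sgrna_dataset`.
#' @param match,mismatch,gap scoring parameters (see [needleman_wunsch()]).
#' @param scaffold scaffold sequence; default is the shipped SpCas9 scaffold.
#' @return a `feature_block`.
#' @export
align_block <- function(dataset, match = 1, mismatch = -1, gap = -1,
                        scaffold = load_scaffold()) {
  sp <- spacers(dataset)
  L <- nchar(sp[1])
  ks <- 5:L
  vals <- t(vapply(sp, function(s) {
    vapply(ks, function(k) {
      .nw_score(substr(s, L - k + 1L, L), scaffold, match, mismatch, gap)
    }, numeric(1))
  }, numeric(length(ks)), USE.NAMES = FALSE))
  feature_block("Align", vals, sprintf("align_k%02d", ks), dataset$id)
}
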